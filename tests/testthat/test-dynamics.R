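test_that("velocity initialization matches equipartition and determinism", {
  big <- build_water_box(7, rng_seed = 1)   # 343 molecules, 1029 atoms
  expect_equal(init_velocities(big, 0), matrix(0, n_atoms(big), 3))
  v <- init_velocities(big, 300, rng_seed = 3)
  expect_identical(v, init_velocities(big, 300, rng_seed = 3))
  m <- atomic_masses(big$species)
  ke <- sum(0.5 * m * rowSums(v^2)) / 9.64853322e-3
  kt_per_dof <- ke / (3 * n_atoms(big)) / (0.5 * 8.617333262e-5 * 300)
  expect_lt(abs(kt_per_dof - 1), 0.03)
  # net linear momentum removed
  expect_lt(max(abs(colSums(v * m))), 1e-10)
})

test_that("harmonic oscillator period matches the closed form within 0.5%", {
  hp <- harmonic_pair_potential(1, 2, k = 1.0, r0 = 1.0)
  cfg <- configuration(c("H", "H"), rbind(c(0, 0, 0), c(1.3, 0, 0)))
  tr <- run_md(cfg, hp, md_params(dt = 0.5, temperature = 0, ensemble = "nve",
                                  duration = 1000, rng_seed = 1),
               frozen_atoms = 1, stride = 1)
  x <- traj_distance(tr, 1, 2)
  cross <- which(diff(sign(x - 1.0)) != 0)
  period <- 2 * mean(diff(tr$times[cross]))
  period_theory <- 2 * pi / sqrt(1.0 / atomic_masses("H") * 9.64853322e-3)
  expect_lt(abs(period - period_theory) / period_theory, 0.005)
})

test_that("NVE conserves energy and the drift shrinks with the timestep", {
  cl <- build_water_cluster(4, rng_seed = 2)
  run_at <- function(dt) {
    tr <- run_md(cl, ref_water,
                 md_params(dt = dt, temperature = 300, ensemble = "nve",
                           duration = 1000, rng_seed = 5), stride = 4)
    et <- tr$epot + tr$ekin
    max(et) - min(et)
  }
  f1 <- run_at(0.5); f2 <- run_at(0.25)
  expect_gt(f1 / f2, 3)   # O(dt^2) energy error: halving dt shrinks ~4x
})

test_that("frozen atoms stay put and zero-spring biases do not change a run", {
  cl <- build_water_cluster(4, rng_seed = 2)
  prm <- md_params(dt = 0.5, temperature = 300, duration = 50, rng_seed = 9)
  tr <- run_md(cl, ref_water, prm, frozen_atoms = 1:3, stride = 1)
  for (i in 1:3) {
    expect_equal(tr$positions[i, , traj_n_frames(tr)], cl$positions[i, ],
                 tolerance = 1e-14)
  }
  b0 <- harmonic_bias(c(1, 4), k = 0, center = 3)
  t1 <- run_md(cl, ref_water, prm, stride = 5)
  t2 <- run_md(cl, ref_water, prm, biases = list(b0), stride = 5)
  expect_identical(t1$positions, t2$positions)
})

test_that("instability aborts with a flagged partial trajectory", {
  # a potential that blows up after a short fuse
  boom <- r_function_potential(function(cf) {
    t <- cf$positions[1, 1]
    list(energy = 0, forces = matrix(ifelse(abs(t) > 0.05, 1e7, 0.1),
                                     n_atoms(cf), 3))
  })
  cfg <- configuration(c("H", "H"), rbind(c(0, 0, 0), c(2, 0, 0)))
  tr <- run_md(cfg, boom, md_params(dt = 0.5, temperature = 300,
                                    duration = 100, rng_seed = 2), stride = 1)
  expect_true(tr$unstable)
  expect_lt(tr$steps_done, 200)
})

test_that("NVT thermostat holds the target temperature", {
  cl <- build_water_cluster(4, rng_seed = 2)
  tr <- run_md(cl, ref_water,
               md_params(dt = 0.5, temperature = 300, ensemble = "nvt",
                         friction = 0.02, duration = 4000, rng_seed = 11),
               stride = 10)
  Ts <- traj_temperature(tr)
  burn <- seq_len(length(Ts) %/% 4)
  expect_lt(abs(mean(Ts[-burn]) - 300), 25)
})

test_that("restrained minimization reaches a stationary point", {
  cl <- build_water_cluster(2, rng_seed = 8)
  res <- minimize_config(cl, ref_water, maxit = 1000)
  expect_true(res$converged)
  expect_lt(res$fmax, 1e-3)
  # with a distance restraint, the restrained coordinate lands near target
  bias <- harmonic_bias(c(1, 4), k = 40, center = 3.2)
  res2 <- minimize_config(cl, ref_water, biases = list(bias), maxit = 1000)
  d <- sqrt(sum((res2$config$positions[1, ] - res2$config$positions[4, ])^2))
  expect_lt(abs(d - 3.2), 0.15)
})
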