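test_that("analytic potentials are stationary at equilibrium and translation invariant", {
  w <- build_water_molecule()
  ev <- evaluate(ref_water, w)
  expect_lt(max(abs(ev$forces)), 1e-8)
  cl <- build_water_cluster(4, rng_seed = 2)
  e1 <- evaluate(ref_water, cl, forces = FALSE)$energy
  moved <- configuration(cl$species, cl$positions + 7.3)
  expect_equal(evaluate(ref_water, moved, forces = FALSE)$energy, e1,
               tolerance = 1e-10)
})

test_that("forces match finite differences and sum to zero", {
  cl <- build_water_cluster(4, rng_seed = 6)
  ev <- evaluate(ref_water, cl)
  expect_lt(max(abs(ev$forces - fd_forces(ref_water, cl))), 1e-6)
  expect_lt(max(abs(colSums(ev$forces))), 1e-8)
  tb <- build_two_bond_system(2.6)
  pot2 <- two_bond_potential()
  ev2 <- evaluate(pot2, tb)
  expect_lt(max(abs(ev2$forces - fd_forces(pot2, tb))), 1e-6)
  expect_lt(max(abs(colSums(ev2$forces))), 1e-10)
})

test_that("two-bond potential has reactant/product minima and an analytic scan", {
  pot <- two_bond_potential()
  p <- pot$params
  r_react <- p$c + p$w
  r_prod <- p$c - p$w
  # well-separated minima and a barrier between them on the symmetric cut
  vr <- two_bond_analytic_pes(pot, r_react, r_react)
  vp <- two_bond_analytic_pes(pot, r_prod, r_prod)
  vt <- two_bond_analytic_pes(pot, p$c, p$c)
  expect_gt(vt, vr)
  expect_gt(vt, vp)
  expect_lt(vp, vr)  # default asymmetry tilts toward the product
})

test_that("KRR interpolates training energies and stays translation invariant", {
  frames <- water_frames(25)
  sp <- soap_params(c("O", "H"), r_cut = 3.5, n_max = 3, l_max = 3)
  m <- train_krr(configuration_set(frames), sp, lambda = 1e-10, zeta = 4,
                 train_on_forces = FALSE)
  pr <- predict(m, frames[[7]], forces = FALSE)
  expect_lt(abs(pr$energy - frames[[7]]$energy), 1e-5)
  moved <- configuration(frames[[3]]$species, frames[[3]]$positions + 4.2)
  expect_equal(predict(m, moved, forces = FALSE)$energy,
               predict(m, frames[[3]], forces = FALSE)$energy,
               tolerance = 1e-9)
  # permutation invariance within species (swap two molecules)
  perm <- c(4:6, 1:3, 7:12)
  swapped <- configuration(frames[[3]]$species[perm],
                           frames[[3]]$positions[perm, ])
  expect_equal(predict(m, swapped, forces = FALSE)$energy,
               predict(m, frames[[3]], forces = FALSE)$energy,
               tolerance = 1e-9)
})

test_that("KRR training validates inputs", {
  frames <- water_frames(5)
  sp <- soap_params(c("O", "H"), r_cut = 3.5, n_max = 3, l_max = 3)
  unlabelled <- configuration_set(lapply(frames, function(cf) {
    configuration(cf$species, cf$positions)
  }))
  expect_error(train_krr(unlabelled, sp), "energies")
  dup <- configuration_set(c(frames[1], frames[1], frames[2]))
  expect_error(train_krr(dup, sp, lambda = 0, train_on_forces = FALSE),
               "lambda")
  m <- train_krr(dup, sp, lambda = 1e-6, train_on_forces = FALSE)
  expect_true(all(is.finite(m$alpha)))
})

test_that("analytic KRR forces agree with finite differences (Richardson)", {
  frames <- water_frames(30)
  sp <- soap_params(c("O", "H"), r_cut = 3.5, n_max = 3, l_max = 3)
  m <- train_krr(configuration_set(frames[1:20]), sp, lambda = 1e-8, zeta = 4)
  cf <- frames[[25]]
  fa <- predict(m, cf)$forces
  m_fd <- m; m_fd$force_method <- "fd"; m_fd$h_fd <- 1e-3
  f1 <- evaluate(m_fd, cf)$forces
  expect_lt(max(abs(fa - f1)), 1e-4)
  # halving h shrinks the FD error roughly 4x (O(h^2))
  m_fd$h_fd <- 5e-4
  f2 <- evaluate(m_fd, cf)$forces
  e1 <- max(abs(f1 - fa)); e2 <- max(abs(f2 - fa))
  expect_lt(e2, e1)
})

test_that("learning curve improves on average with training size", {
  frames <- water_frames(60)
  sp <- soap_params(c("O", "H"), r_cut = 3.5, n_max = 3, l_max = 3)
  test_set <- configuration_set(frames[41:60])
  mads <- vapply(c(10, 40), function(ntr) {
    m <- train_krr(configuration_set(frames[1:ntr]), sp, lambda = 1e-9,
                   zeta = 4)
    mad_metrics(m, ref_water, test_set)$mad_energy
  }, numeric(1))
  expect_lt(mads[2], mads[1])
})

test_that("MAD metrics match a hand-rolled mean and detect offsets", {
  frames <- water_frames(3)
  es <- configuration_set(frames)
  zero <- mad_metrics(ref_water, ref_water, es)
  expect_equal(zero$mad_energy, 0)
  expect_equal(zero$mad_forces, 0)
  offset <- r_function_potential(function(cf) {
    r <- evaluate(ref_water, cf)
    r$energy <- r$energy + 1 / 23.0605   # +1 kcal/mol
    r
  })
  off <- mad_metrics(offset, ref_water, es)
  expect_equal(off$mad_energy, 1, tolerance = 1e-9)
  expect_equal(off$mad_forces, 0)
  # hand-rolled oracle on a 3-config fixture
  skew <- r_function_potential(function(cf) {
    r <- evaluate(ref_water, cf)
    list(energy = r$energy + 0.01 * n_atoms(cf), forces = r$forces + 0.002)
  })
  mm <- mad_metrics(skew, ref_water, es)
  expect_equal(mm$mad_energy, 0.01 * 12 * 23.0605, tolerance = 1e-9)
  expect_equal(mm$mad_forces, 0.002 * 23.0605, tolerance = 1e-9)
  expect_error(mad_metrics(ref_water, ref_water, configuration_set()), "empty")
})

test_that("model serialization round trips and guards the descriptor hash", {
  frames <- water_frames(10)
  sp <- soap_params(c("O", "H"), r_cut = 3.5, n_max = 3, l_max = 3)
  m <- train_krr(configuration_set(frames), sp, lambda = 1e-8, zeta = 4,
                 train_on_forces = FALSE)
  path <- tempfile(fileext = ".json")
  save_mlp(m, path)
  back <- load_mlp(path, expect_params = sp)
  cf <- frames[[2]]
  expect_equal(predict(back, cf, forces = FALSE)$energy,
               predict(m, cf, forces = FALSE)$energy, tolerance = 1e-10)
  other <- soap_params(c("O", "H"), r_cut = 4.0, n_max = 3, l_max = 3)
  expect_error(load_mlp(path, expect_params = other), "hash mismatch")
})
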