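tb_pot <- two_bond_potential()
tb_rc <- reaction_coordinate(c(1L, 3L), c(2L, 4L))

test_that("state classification uses the 1.6/3.0 A thresholds", {
  expect_identical(classify_state(1.5, 1.55), "product")
  expect_identical(classify_state(3.2, 3.5), "reactant")
  expect_identical(classify_state(1.5, 2.5), "ongoing")
  expect_identical(classify_state(c(1, 4), c(1.2, 4)), c("product", "reactant"))
  expect_error(classify_state(-1, 2), "positive")
})

test_that("bond-formation times and the 60 fs gap come from first crossings", {
  # synthetic trajectory: r1 crosses 1.6 A at 100 fs, r2 at 150 fs
  times <- seq(0, 400, by = 2)
  r1 <- ifelse(times < 100, 2.5, 1.4)
  r2 <- ifelse(times < 150, 2.5, 1.4)
  pos <- array(0, c(4, 3, length(times)))
  pos[2, 1, ] <- 1.4
  pos[3, 2, ] <- r1
  pos[4, 1, ] <- 1.4; pos[4, 2, ] <- r2
  traj <- structure(list(positions = pos, times = times, species = rep("C", 4)),
                    class = "trajectory")
  an <- mlal:::analyze_reactive_traj(traj, tb_rc)
  expect_equal(an$t_r1, 100)
  expect_equal(an$t_r2, 150)
  expect_equal(an$time_gap, 50)
  expect_true(an$concerted)        # 50 fs < 60 fs criterion
  expect_identical(an$outcome, "product")
})

test_that("downhill dynamics from a product-tilted saddle reach the product", {
  ts <- build_two_bond_system(tb_pot$params$c - 0.05)
  pool <- configuration_set(lapply(1:3, function(i) ts))
  res <- downhill_ensemble(pool, tb_pot, tb_rc,
                           md_params(dt = 0.5, temperature = 150, rng_seed = 3),
                           max_time = 1500)
  expect_gt(res$summary$n_product, 0)
  formed <- res$outcomes[res$outcomes$outcome == "product", ]
  expect_true(all(is.finite(formed$time_gap)))
  # relabelling the two bond pairs leaves |gap| statistics unchanged
  rc_sw <- reaction_coordinate(c(2L, 4L), c(1L, 3L))
  res_sw <- downhill_ensemble(pool, tb_pot, rc_sw,
                              md_params(dt = 0.5, temperature = 150,
                                        rng_seed = 3), max_time = 1500)
  expect_equal(res_sw$outcomes$time_gap, res$outcomes$time_gap)
  expect_identical(res_sw$outcomes$outcome, res$outcomes$outcome)
})

test_that("relaxed 2D scan reproduces the analytic constrained surface", {
  start <- build_two_bond_system(2.4)
  r1g <- seq(1.9, 2.9, length.out = 4)
  r2g <- seq(1.9, 2.9, length.out = 4)
  scan <- relaxed_scan_2d(tb_pot, start, tb_rc, r1g, r2g, restraint_k = 600)
  expect_true(all(scan$converged))
  exact <- outer(r1g, r2g, function(a, b) two_bond_analytic_pes(tb_pot, a, b))
  expect_lt(max(abs(scan$energies - exact)), 0.01)
  # reversing the grid direction gives the same surface
  scan_rev <- relaxed_scan_2d(tb_pot, start, tb_rc, rev(r1g), rev(r2g),
                              restraint_k = 600)
  expect_lt(max(abs(scan_rev$energies[4:1, 4:1] - scan$energies)), 0.02)
  expect_error(relaxed_scan_2d(tb_pot, start, tb_rc, c(1, 3, 2), r2g), "monotone")
})

test_that("a stiff umbrella window samples the closed-form Gaussian variance", {
  kap <- 2; kw <- 20
  pot <- harmonic_pair_potential(1, 2, k = kap, r0 = 2.0)
  cfg <- configuration(c("O", "O"), rbind(c(0, 0, 0), c(2.0, 0, 0)))
  rc <- reaction_coordinate(c(1L, 2L), c(1L, 2L))
  win <- run_umbrella(pot, rc, data.frame(center = 2.0, k = kw),
                      md_params(dt = 0.5, temperature = 300,
                                duration = 40000, rng_seed = 4), cfg)
  v <- var(win[[1]]$xi)
  v_theory <- 8.617333262e-5 * 300 / (kap + kw)
  expect_lt(abs(v - v_theory) / v_theory, 0.2)
})

test_that("disjoint windows on a steep potential raise an overlap error", {
  pot <- harmonic_pair_potential(1, 2, k = 60, r0 = 2.0)
  cfg <- configuration(c("O", "O"), rbind(c(0, 0, 0), c(2.0, 0, 0)))
  rc <- reaction_coordinate(c(1L, 2L), c(1L, 2L))
  expect_error(
    run_umbrella(pot, rc, data.frame(center = c(1.2, 3.6), k = c(300, 300)),
                 md_params(dt = 0.5, temperature = 50, duration = 2000,
                           rng_seed = 2), cfg),
    "overlap")
})

test_that("WHAM recovers a flat profile from unbiased samples", {
  set.seed(9)
  windows <- list(structure(list(center = 2, k = 0,
                                 xi = runif(40000, 1, 3), temperature = 300),
                            class = "umbrella_window"))
  fes <- reconstruct_fes(windows, n_bins = 20)
  rng <- range(fes$free_energy, na.rm = TRUE)
  expect_lt(rng[2] - rng[1], 0.12)   # kcal/mol, sampling noise only
})

test_that("umbrella windows tile a double well and WHAM matches quadrature", {
  pot <- double_well_pair_potential(1, 2, barrier = 0.25, centre = 2.2,
                                    width = 0.5)
  cfg <- configuration(c("O", "O"), rbind(c(0, 0, 0), c(2.7, 0, 0)))
  rc <- reaction_coordinate(c(1L, 2L), c(1L, 2L))
  spec <- data.frame(center = seq(1.6, 2.9, length.out = 12), k = 15)
  md <- md_params(dt = 0.5, temperature = 300, duration = 20000, rng_seed = 1)
  wins <- run_umbrella(pot, rc, spec, md, cfg)
  # coverage: sampled xi ranges tile the window span
  allxi <- sort(unlist(lapply(wins, `[[`, "xi")))
  expect_lt(max(diff(allxi)), 0.05)
  fes <- reconstruct_fes(wins, n_bins = 80)
  # quadrature oracle: F(r) = U(r) - 2 kT log r, min-shifted, same barrier rule
  kT <- 8.617333262e-5 * 300
  r <- seq(min(allxi), max(allxi), length.out = 2000)
  U <- 0.25 * ((r - 2.2)^2 - 0.25)^2 / 0.0625
  Fq <- (U - 2 * kT * log(r)) * 23.0605
  Fq <- Fq - min(Fq)
  basin_lo <- which.min(Fq[r < 2.2])
  basin_hi <- which.min(Fq[r > 2.2]) + sum(r <= 2.2)
  ts_i <- which.max(Fq[basin_lo:basin_hi]) + basin_lo - 1L
  barrier_q <- Fq[ts_i] - Fq[basin_hi]   # reactant basin at large r
  expect_lt(abs(fes$barrier - barrier_q), 0.35)  # single-seed sanity bound
  expect_equal(min(fes$free_energy, na.rm = TRUE), 0)
})

test_that("RDF is normalized against the ideal gas and counts crystal shells", {
  # ideal gas: uniform random points in a periodic box, free potential
  set.seed(10)
  L <- 12
  pos <- matrix(runif(3 * 400, 0, L), ncol = 3)
  cfg <- configuration(rep("O", 400), pos, cell = diag(3) * L, periodic = TRUE)
  tr <- run_md(cfg, free_potential(),
               md_params(dt = 0.5, temperature = 0, ensemble = "nve",
                         duration = 0, rng_seed = 1), stride = 1)
  g <- rdf(tr, c("O", "O"), r_max = 5, n_bins = 8)
  expect_lt(max(abs(g$g[-1] - 1)), 0.2)
  expect_error(rdf(tr, c("O", "O"), r_max = 7), "half")
  # two atoms at 3.0 A: a single populated bin
  cfg2 <- configuration(rep("O", 2), rbind(c(0, 0, 0), c(3, 0, 0)),
                        cell = diag(3) * 20, periodic = TRUE)
  tr2 <- run_md(cfg2, free_potential(),
                md_params(dt = 0.5, temperature = 0, ensemble = "nve",
                          duration = 0, rng_seed = 1), stride = 1)
  g2 <- rdf(tr2, c("O", "O"), r_max = 5, n_bins = 25)
  expect_equal(sum(g2$g > 0), 1L)
  expect_equal(g2$r[g2$g > 0], 3.1, tolerance = 0.11)
  # simple cubic crystal: first coordination shell integrates to 6 exactly
  a <- 3
  lat <- as.matrix(expand.grid(0:3, 0:3, 0:3)) * a
  cfg3 <- configuration(rep("O", nrow(lat)), lat, cell = diag(3) * 4 * a,
                        periodic = TRUE)
  tr3 <- run_md(cfg3, free_potential(),
                md_params(dt = 0.5, temperature = 0, ensemble = "nve",
                          duration = 0, rng_seed = 1), stride = 1)
  g3 <- rdf(tr3, c("O", "O"), r_max = 5, n_bins = 50)
  rho <- nrow(lat) / (4 * a)^3
  shell <- g3$r <= 3.5
  coord <- sum(4 * pi * g3$r[shell]^2 * g3$g[shell] * rho * diff(c(0, g3$r))[shell])
  expect_equal(coord, 6, tolerance = 0.05)
})

test_that("hydrogen bonds follow the geometric criterion", {
  expect_equal(nrow(find_hbonds(build_water_molecule())), 0L)
  # ideal dimer: donor O-H pointing at the acceptor O
  d <- build_water_molecule()
  acc <- build_water_molecule(origin = c(0, 0, 0))
  # place acceptor O along the first O-H bond of the donor, 2.9 A from O_d
  dirv <- d$positions[2, ] - d$positions[1, ]
  dirv <- dirv / sqrt(sum(dirv^2))
  shift <- d$positions[1, ] + 2.9 * dirv - acc$positions[1, ]
  acc_pos <- sweep(acc$positions, 2, shift, "+")
  dimer <- configuration(c(d$species, acc$species),
                         rbind(d$positions, acc_pos))
  hb <- find_hbonds(dimer)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$donor_o, 1L)
  expect_equal(hb$acceptor_o, 4L)
  expect_lt(hb$dist, 3.5)
  expect_gt(hb$angle, 140)
  expect_error(hb_criterion(angle_cut = 80), "90")
})

test_that("per-shell hydrogen-bond counts report empty bins as missing", {
  d <- build_water_molecule()
  tr <- run_md(d, ref_water, md_params(dt = 0.5, temperature = 100,
                                       duration = 10, rng_seed = 1),
               stride = 10)
  out <- count_hbs_by_distance(tr, shell_bins = c(0, 2, 50, 100))
  expect_equal(out$mean_hbs[out$n_obs > 0], 0)   # isolated water: no HBs
  expect_true(is.na(out$mean_hbs[3]))            # far bin has no molecules
})

test_that("reactant-pool restraint centres outside [3, 5] A are rejected", {
  start <- build_two_bond_system(3.4)
  expect_error(prepare_rs_pool(start, tb_pot, tb_rc,
                               restraint_centers = c(2.0, 3.5)),
               "\\[3.0, 5.0\\]")
})

test_that("uphill bias drives product formation where the unbiased control stalls", {
  soft <- two_bond_potential(barrier = 0.2)
  start <- build_two_bond_system(3.3)
  rs <- prepare_rs_pool(start, soft, tb_rc, restraint_centers = c(3.3, 3.3),
                        restraint_k = 2,
                        md = md_params(dt = 0.5, temperature = 300,
                                       rng_seed = 5),
                        n_snapshots = 3, snapshot_interval = 200)
  md <- md_params(dt = 0.5, temperature = 300, rng_seed = 6)
  biased <- uphill_ensemble(rs, soft, tb_rc, md, bias_k = 0.4,
                            target_xi = 1.5, max_time = 3000)
  control <- uphill_ensemble(rs, soft, tb_rc, md, bias_k = 0,
                             target_xi = 1.5, max_time = 3000)
  expect_gt(sum(biased$outcomes$outcome == "product"),
            sum(control$outcomes$outcome == "product"))
  expect_true(all(control$outcomes$outcome == "timeout"))
})
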