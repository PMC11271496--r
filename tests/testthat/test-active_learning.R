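test_that("episode schedule follows n^3 + 2 and the 5 ps cap", {
  expect_equal(md_schedule(0), 2)
  expect_equal(md_schedule(2), 10)
  expect_equal(md_schedule(0:4), c(2, 3, 10, 29, 66))
  expect_equal(md_schedule(17), 4915)
  expect_lte(md_schedule(17), 5000)
  expect_gt(md_schedule(18), 5000)
  expect_error(md_schedule(-1), ">= 0")
})

test_that("degenerate selectors terminate the loop via the time cap", {
  sp <- soap_params(c("O", "H"), r_cut = 3.0, n_max = 2, l_max = 1)
  cl <- build_water_cluster(2, rng_seed = 3)
  init <- random_displace(cl, 0.05, 4, rng_seed = 5)
  # k_T = 0 never fires: streak runs 2, 3, 10, ..., 4915 then terminates
  cfg <- al_config("similarity",
                   similarity_selector_config(k_T = 1e-12, zeta = 4),
                   soap = sp, temperature = 100, rng_seed = 1,
                   max_label_energy_per_atom = NULL)
  res <- al_train(init, ref_water, cfg)
  expect_true(res$converged)
  expect_equal(length(res$training_set), 4L)
  expect_equal(res$log$duration, md_schedule(0:17))
  expect_true(all(res$log$verdict == "skip"))
  # huge E_T on the energy selector: identical termination pattern
  cfg2 <- al_config("energy", energy_selector_config(E_T = 1e6),
                    soap = sp, temperature = 100, rng_seed = 1,
                    max_label_energy_per_atom = NULL)
  res2 <- al_train(init, ref_water, cfg2)
  expect_true(res2$converged)
  expect_equal(nrow(res2$log), 18L)
  expect_equal(res2$reference_calls, 18L)  # energy selector labels every frame
})

test_that("accepted structures carry provenance and reset the streak", {
  sp <- soap_params(c("O", "H"), r_cut = 3.0, n_max = 2, l_max = 1)
  cl <- build_water_cluster(2, rng_seed = 3)
  init <- random_displace(cl, 0.05, 4, rng_seed = 5)
  # k_T = 1 is degenerate: any non-identical candidate is added
  cfg <- al_config("similarity", similarity_selector_config(k_T = 1, zeta = 4),
                   soap = sp, temperature = 200, rng_seed = 2,
                   max_al_iterations = 6L, max_label_energy_per_atom = NULL)
  res <- al_train(init, ref_water, cfg)
  expect_false(res$converged)  # stopped by the iteration cap, not the 5 ps rule
  added <- res$training_set$configs[-(1:4)]
  expect_gt(length(added), 0L)
  for (cf in added) {
    expect_identical(cf$provenance$verdict, "add")
    expect_identical(cf$provenance$selector, "similarity")
    expect_identical(cf$label, "reference")
  }
  expect_true(all(res$log$n == 0))  # every acceptance resets n
})

test_that("al_train is reproducible and logs decisions as JSON lines", {
  sp <- soap_params(c("O", "H"), r_cut = 3.0, n_max = 2, l_max = 1)
  cl <- build_water_cluster(2, rng_seed = 3)
  init <- random_displace(cl, 0.05, 4, rng_seed = 5)
  cfg <- al_config("similarity", similarity_selector_config(0.995, 4),
                   soap = sp, temperature = 150, rng_seed = 7,
                   max_al_iterations = 10L)
  r1 <- al_train(init, ref_water, cfg)
  r2 <- al_train(init, ref_water, cfg)
  expect_identical(r1$log$score, r2$log$score)
  expect_identical(r1$model$alpha, r2$model$alpha)
  path <- tempfile(fileext = ".jsonl")
  write_decision_log(r1$log, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(r1$log))
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("iteration", "selector", "score", "threshold", "verdict")
                  %in% names(rec)))
})

test_that("distance selector demands a sufficiently large initial set", {
  sp <- soap_params(c("O", "H"), r_cut = 3.0, n_max = 2, l_max = 1)
  cl <- build_water_cluster(2, rng_seed = 3)
  init <- random_displace(cl, 0.05, 4, rng_seed = 5)
  cfg <- al_config("distance", distance_selector_config(k = 10),
                   soap = sp, rng_seed = 1)
  expect_error(al_train(init, ref_water, cfg), "min_initial_size")
})

test_that("subset jobs are independent, tagged, and deduplicated on merge", {
  sp <- soap_params(c("O", "H"), r_cut = 3.0, n_max = 2, l_max = 1)
  solvent <- build_water_cluster(2, rng_seed = 1)
  cfg <- al_config("similarity", similarity_selector_config(0.9, 4),
                   soap = sp, temperature = 100, rng_seed = 3,
                   max_al_iterations = 2L)
  expect_error(build_subsets(list(subsets = list(pure_solvent = list())), cfg),
               "start structure")
  # single pure-solvent subset -> one job from the solvent configuration
  jobs <- build_subsets(list(subsets = list(
    pure_solvent = list(start = solvent, n_initial = 5))), cfg)
  expect_length(jobs, 1L)
  expect_equal(length(jobs$pure_solvent$initial_set), 5L)
  expect_identical(jobs$pure_solvent$initial_set[[2]]$provenance$subset,
                   "pure_solvent")
  # two subsets with identical starts: merged set deduplicates exact
  # descriptor duplicates (the shared seed configuration appears once)
  jobs2 <- build_subsets(list(subsets = list(
    a = list(start = solvent, n_initial = 3),
    b = list(start = solvent, n_initial = 3))), cfg)
  res <- al_train_subsets(jobs2, ref_water)
  tags <- vapply(res$training_set$configs,
                 function(cf) cf$provenance$subset, character(1))
  expect_setequal(unique(tags), c("a", "b"))
  expect_equal(length(res$training_set) + res$n_duplicates_removed,
               sum(vapply(res$runs, function(r) length(r$training_set),
                          integer(1))))
})
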