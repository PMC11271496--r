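test_that("configuration validates atom counts, finiteness and labels", {
  expect_error(configuration(c("O", "H"), rbind(c(0, 0, 0))), "atom counts")
  expect_error(configuration("H", rbind(c(NA, 0, 0))), "finite")
  expect_error(configuration("H", rbind(c(0, 0, 0)), energy = 1), "label")
  expect_error(configuration("H", rbind(c(0, 0, 0)), periodic = TRUE), "cell")
  expect_error(configuration("H", rbind(c(0, 0, 0)), cell = matrix(0, 3, 3),
                             periodic = TRUE), "singular")
  cf <- configuration(c("O", "H", "H"),
                      rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
                      energy = -1.5, forces = matrix(0, 3, 3),
                      label = "reference")
  expect_equal(n_atoms(cf), 3L)
  expect_identical(cf$label, "reference")
})

test_that("configuration sets append and split deterministically", {
  set <- configuration_set(lapply(1:6, function(i) {
    configuration("H", rbind(c(i, 0, 0)))
  }))
  grown <- append_config(set, configuration("H", rbind(c(9, 9, 9))), "added")
  expect_equal(length(grown), 7L)
  expect_equal(length(set), 6L)
  s1 <- split_set(set, 0.5, seed = 7)
  s2 <- split_set(set, 0.5, seed = 7)
  expect_identical(vapply(s1$train$configs, function(x) x$positions[1], numeric(1)),
                   vapply(s2$train$configs, function(x) x$positions[1], numeric(1)))
  expect_equal(length(s1$train) + length(s1$heldout), 6L)
})

test_that("extended-XYZ round trip preserves all fields", {
  w <- build_water_molecule()
  w <- set_labels(w, energy = -2.123456789012, forces = matrix(runif(9), 3),
                  label = "reference")
  box <- build_water_box(2, rng_seed = 1)
  path <- tempfile(fileext = ".xyz")
  write_extxyz(configuration_set(list(w, box)), path)
  back <- read_extxyz(path)
  expect_equal(length(back), 2L)
  expect_identical(back[[1]]$species, w$species)
  expect_lt(max(abs(back[[1]]$positions - w$positions)), 1e-8)
  expect_equal(back[[1]]$energy, w$energy, tolerance = 1e-12)
  expect_lt(max(abs(back[[1]]$forces - w$forces)), 1e-10)
  expect_true(back[[2]]$periodic)
  expect_lt(max(abs(back[[2]]$cell - box$cell)), 1e-8)
  expect_null(back[[2]]$forces)
})

test_that("malformed extxyz frames raise errors naming the frame", {
  path <- tempfile(fileext = ".xyz")
  writeLines(c("5", "Properties=species:S:1:pos:R:3",
               "O 0 0 0", "H 1 0 0", "H 0 1 0", "H 1 1 0"), path)
  expect_error(read_extxyz(path), "frame 1")
  writeLines(c("2", "Properties=species:S:1:pos:R:3",
               "O 0 0 0", "H x 0 0"), path)
  expect_error(read_extxyz(path), "non-numeric")
})

test_that("random displacement respects bounds, determinism and zero case", {
  seed_cf <- build_water_molecule()
  expect_error(random_displace(seed_cf, count = 0), "count")
  expect_error(random_displace(seed_cf, max_disp = -1), "non-negative")
  zero <- random_displace(seed_cf, max_disp = 0, count = 3, rng_seed = 1)
  for (cf in zero$configs) expect_identical(cf$positions, seed_cf$positions)
  a <- random_displace(seed_cf, 0.1, 20, rng_seed = 5)
  b <- random_displace(seed_cf, 0.1, 20, rng_seed = 5)
  expect_identical(a[[7]]$positions, b[[7]]$positions)
  deltas <- vapply(a$configs, function(cf) max(abs(cf$positions - seed_cf$positions)),
                   numeric(1))
  expect_true(all(deltas <= 0.1))
  expect_true(all(deltas > 0))
  expect_identical(a[[1]]$provenance$subset, "initial")
})

test_that("cluster carving enforces the shell >= cutoff rule and keeps molecules whole", {
  box <- build_water_box(3, rng_seed = 2)
  expect_error(carve_cluster(box, 1:3, r_cluster = 4, r_cut = 5),
               "no less than the cut-off")
  expect_error(carve_cluster(box, c(0, 1), 5, 5), "out of range")
  # solute alone in vacuum: cluster equals solute
  w <- build_water_molecule()
  solo <- carve_cluster(w, 1:3, 3.5, 3.5)
  expect_equal(solo$positions, w$positions, tolerance = 1e-12)
  # brute-force count oracle on a periodic box
  r_cl <- 3.5
  carved <- carve_cluster(box, 1:3, r_cl, 3.0)
  expect_equal(n_atoms(carved) %% 3L, 0L)
  # oracle: molecules with any atom within r_cl of any solute atom (min image)
  d <- pair_distances_oracle(box)
  mol <- rep(seq_len(n_atoms(box) / 3L), each = 3L)
  keep <- unique(mol[apply(d[, 1:3, drop = FALSE], 1L, min) <= r_cl])
  expect_equal(n_atoms(carved) / 3L, length(keep))
  # included atoms' bonded partners are included (never split)
  expect_false(carved$periodic)
})
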