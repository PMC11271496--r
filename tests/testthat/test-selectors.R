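test_that("energy selector partitions errors into skip/add/discard", {
  cfg <- energy_selector_config(E_T = 1)
  expect_identical(energy_select(10, 9.5, cfg)$verdict, "skip")
  expect_identical(energy_select(10, 5, cfg)$verdict, "add")
  expect_identical(energy_select(10, -5, cfg)$verdict, "discard")
  # boundary semantics: [0, E_T] skip, (E_T, 10 E_T] add, beyond discard
  expect_identical(energy_select(1, 0, cfg)$verdict, "skip")
  expect_identical(energy_select(10, 0, cfg)$verdict, "add")
  expect_identical(energy_select(10 + 1e-9, 0, cfg)$verdict, "discard")
  expect_error(energy_select(NA, 0, cfg), "reference")
  expect_error(energy_selector_config(-1), "positive")
})

test_that("similarity selector thresholds max kernel and is monotone in k_T", {
  tr <- rand_unit_rows(10, 6, seed = 2)
  p_id <- tr[4, ]
  for (kT in c(0.5, 0.9, 1.0)) {
    dec <- similarity_select(p_id, tr, similarity_selector_config(kT, 4))
    expect_identical(dec$verdict, "skip")   # identical structure never added
  }
  # candidate orthogonal to every training vector (QR complement)
  tr_small <- rand_unit_rows(4, 6, seed = 8)
  qq <- qr.Q(qr(t(tr_small)), complete = TRUE)[, 5]
  dec <- similarity_select(qq, tr_small, similarity_selector_config(0.9995, 4))
  expect_identical(dec$verdict, "add")
  expect_equal(dec$score, 0, tolerance = 1e-20)
  # monotonicity: raising k_T never flips add -> skip
  p <- rand_unit_rows(1, 6, seed = 33)[1, ]
  kts <- seq(0.05, 1, by = 0.05)
  verdicts <- vapply(kts, function(kT) {
    similarity_select(p, tr, similarity_selector_config(kT, 4))$verdict
  }, character(1))
  first_add <- match("add", verdicts)
  if (!is.na(first_add)) {
    expect_true(all(verdicts[first_add:length(kts)] == "add"))
  }
})

test_that("LOF of a uniform-grid interior point is exactly 1", {
  g <- as.matrix(expand.grid(x = -10:10, y = -10:10))
  centre_idx <- which(g[, 1] == 0 & g[, 2] == 0)
  rep <- lof_profile(g[centre_idx, ], g, k = 8)
  expect_identical(rep$lof, 1)
  expect_equal(as.numeric(lof_profile(g[centre_idx, ], g, k = 4)$lof), 1)
})

test_that("LOF flags outliers (>1) and inliers (<1)", {
  set.seed(4)
  cloud <- matrix(rnorm(240, sd = 0.3), ncol = 2)
  far <- c(5, 5)
  expect_gt(lof_profile(far, cloud, k = 10)$lof, 1)
  # dense-core point of a radially decaying cloud
  set.seed(5)
  r <- abs(rnorm(150, sd = 1.2)) + 0.05
  ang <- runif(150, 0, 2 * pi)
  cloud2 <- cbind(r * cos(ang), r * sin(ang))
  expect_lt(lof_profile(c(0.01, 0.0), cloud2, k = 10)$lof, 1)
})

test_that("LOF matches the brute-force oracle to 1e-10 on random clouds", {
  for (case in list(list(n = 60, k = 5, seed = 11), list(n = 150, k = 10, seed = 12),
                    list(n = 200, k = 20, seed = 13))) {
    set.seed(case$seed)
    X <- matrix(rnorm(case$n * 3), ncol = 3)
    for (qseed in 1:3) {
      set.seed(100 + qseed)
      o <- rnorm(3)
      expect_equal(lof_profile(o, X, k = case$k)$lof, brute_lof(o, X, case$k),
                   tolerance = 1e-10)
    }
    # member of the dataset (leave-self-out)
    expect_equal(lof_profile(X[7, ], X, k = case$k)$lof,
                 brute_lof(X[7, ], X, case$k), tolerance = 1e-10)
  }
})

test_that("LOF threshold uses the lower nearest-rank 80th percentile", {
  set.seed(21)
  X <- matrix(rnorm(40), ncol = 2)
  thr <- lof_threshold(X, k = 5, percentile = 80)
  lofs <- attr(thr, "lof_values")
  expect_equal(as.numeric(thr), sort(lofs)[ceiling(0.8 * 20)])
  # brute-force re-derivation
  brute <- sort(vapply(seq_len(20), function(i) brute_lof(X[i, ], X, 5),
                       numeric(1)))[16]
  expect_equal(as.numeric(thr), brute, tolerance = 1e-10)
  expect_error(lof_threshold(X[1:4, ], k = 5), "min_initial_size")
})

test_that("distance selector composes lof_profile with lof_threshold", {
  set.seed(31)
  X <- matrix(rnorm(120), ncol = 2)
  cfg <- distance_selector_config(k = 8)
  expect_error(distance_select(c(0, 0), X[1:5, ], cfg), "min_initial_size")
  dec_out <- distance_select(c(30, 30), X, cfg)
  expect_identical(dec_out$verdict, "add")
  dec_in <- distance_select(X[4, ], X, cfg)
  thr <- lof_threshold(X, k = 8, percentile = 80)
  lof <- lof_profile(X[4, ], X, k = 8)$lof
  expect_identical(dec_in$verdict, if (lof > as.numeric(thr)) "add" else "skip")
  expect_equal(dec_in$score, lof, tolerance = 1e-12)
  # duplicates collapsed rather than erroring
  dec_dup <- distance_select(X[4, ], rbind(X, X[1, ]), cfg)
  expect_equal(dec_dup$score, lof, tolerance = 1e-12)
  expect_error(lof_profile(X[1, ], rbind(X, X[2, ]), 8), "deduplicate")
})
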