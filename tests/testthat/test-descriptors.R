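sp_small <- soap_params(c("O", "H"), r_cut = 3.5, n_max = 3, l_max = 3)

test_that("global SOAP vectors are unit-norm, deterministic, and invariant", {
  cl <- build_water_cluster(4, rng_seed = 1)
  p <- compute_soap(cl, sp_small)
  expect_equal(sum(as.numeric(p)^2), 1, tolerance = 1e-10)
  expect_identical(as.numeric(p), as.numeric(compute_soap(cl, sp_small)))
  # rotation + translation
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- configuration(cl$species, cl$positions %*% t(R) + 5)
  expect_lt(max(abs(as.numeric(p) - as.numeric(compute_soap(moved, sp_small)))),
            1e-8)
  # permutation of same-species atoms (swap two whole water molecules)
  perm <- c(4:6, 1:3, 7:n_atoms(cl))
  swapped <- configuration(cl$species[perm], cl$positions[perm, ])
  expect_lt(max(abs(as.numeric(p) - as.numeric(compute_soap(swapped, sp_small)))),
            1e-10)
  expect_error(compute_soap(configuration("Ar", rbind(c(0, 0, 0))), sp_small),
               "Ar")
})

test_that("kernel obeys closed-form values and zeta monotonicity", {
  expect_equal(soap_kernel(c(1, 0), c(1, 0), 4), 1.0)
  expect_equal(soap_kernel(c(1, 0), c(0, 1), 4), 0.0)
  expect_equal(soap_kernel(c(1, 0), c(0.9, sqrt(1 - 0.81)), 4), 0.6561,
               tolerance = 1e-12)
  expect_error(soap_kernel(c(1, 0), c(1, 0, 0), 2), "mismatch")
  expect_error(soap_kernel(c(1, 0), c(1, 0), 0), "positive integer")
  # monotone decreasing in zeta for 0 < dot < 1
  p <- c(1, 0); q <- c(0.95, sqrt(1 - 0.95^2))
  ks <- vapply(1:6, function(z) soap_kernel(p, q, z), numeric(1))
  expect_true(all(diff(ks) < 0))
  # distinct geometries give kernel strictly below 1
  p1 <- compute_soap(build_water_cluster(4, rng_seed = 1), sp_small)
  p2 <- compute_soap(build_water_cluster(4, rng_seed = 9), sp_small)
  expect_lt(soap_kernel(p1, p2, 4), 1)
})

test_that("similarity vector matches a brute-force oracle", {
  cl <- lapply(c(1, 5, 9, 13), function(s) build_water_cluster(4, rng_seed = s))
  descs <- lapply(cl, compute_soap, params = sp_small)
  p0 <- descs[[3]]
  K <- similarity_vector(p0, descs, zeta = 4)
  expect_length(K, 4L)
  expect_equal(K[3], 1.0, tolerance = 1e-12)
  expect_equal(attr(K, "max"), 1.0, tolerance = 1e-12)
  brute <- vapply(descs, function(q) abs(sum(as.numeric(p0) * as.numeric(q)))^4,
                  numeric(1))
  expect_equal(as.numeric(K), brute, tolerance = 1e-12)
  expect_length(similarity_vector(p0, descs[1], 4), 1L)
  expect_error(similarity_vector(p0, list(), 4), "empty")
})
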