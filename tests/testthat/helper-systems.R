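# Small systems and oracles shared across tests.

ref_water <- toy_water_potential()

# finite-difference forces for any potential (independent oracle)
fd_forces <- function(potential, config, h = 1e-4) {
  n <- n_atoms(config)
  F <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    for (d in 1:3) {
      pp <- config$positions; pp[i, d] <- pp[i, d] + h
      pm <- config$positions; pm[i, d] <- pm[i, d] - h
      ep <- evaluate(potential,
                     configuration(config$species, pp, config$cell,
                                   config$periodic), forces = FALSE)$energy
      em <- evaluate(potential,
                     configuration(config$species, pm, config$cell,
                                   config$periodic), forces = FALSE)$energy
      F[i, d] <- -(ep - em) / (2 * h)
    }
  }
  F
}

# brute-force LOF oracle, written independently of lof_profile():
# plain loops, matrix distances, no shared helpers.
brute_lof <- function(o, X, k) {
  n <- nrow(X)
  d_full <- as.matrix(dist(X))
  kdist <- numeric(n)
  for (i in seq_len(n)) {
    kdist[i] <- sort(d_full[i, -i])[k]
  }
  knn_of <- function(dvec, excl) {
    ord <- order(dvec)
    ord <- ord[!(ord %in% excl)]
    ord[seq_len(k)]
  }
  lrd_of_point <- function(dvec, excl) {
    nb <- knn_of(dvec, excl)
    rd <- pmax(kdist[nb], dvec[nb])
    1 / mean(rd)
  }
  d_o <- sqrt(colSums((t(X) - o)^2))
  self <- which(d_o < 1e-12)
  lrd_o <- lrd_of_point(d_o, self)
  nb_o <- knn_of(d_o, self)
  lrd_nb <- vapply(nb_o, function(a) lrd_of_point(d_full[a, ], a), numeric(1))
  mean(lrd_nb) / lrd_o
}

# labelled thermal frames of a small water cluster (cached per session)
water_frames <- local({
  cache <- NULL
  function(n = 60) {
    if (is.null(cache)) {
      cl <- minimize_config(build_water_cluster(4, rng_seed = 3), ref_water,
                            maxit = 1000)$config
      tr <- run_md(cl, ref_water,
                   md_params(dt = 0.5, temperature = 300, duration = 800,
                             rng_seed = 42), stride = 10)
      cache <<- lapply(seq_len(traj_n_frames(tr))[-1], function(i) {
        cf <- traj_frame(tr, i)
        r <- evaluate(ref_water, cf)
        set_labels(cf, r$energy, r$forces, "reference")
      })
    }
    cache[seq_len(min(n, length(cache)))]
  }
})

rand_unit_rows <- function(n, d, seed) {
  set.seed(seed)
  M <- matrix(rnorm(n * d), n, d)
  M / sqrt(rowSums(M^2))
}

# independent min-image distance oracle (vs package internals)
pair_distances_oracle <- function(config) {
  n <- n_atoms(config)
  L <- diag(config$cell)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dv <- config$positions[j, ] - config$positions[i, ]
    dv <- dv - round(dv / L) * L
    d[i, j] <- sqrt(sum(dv^2))
  }
  d
}
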