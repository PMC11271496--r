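#' Selector configurations
#'
#' The three structure selectors driving active learning:
#' * the *energy* selector adds a candidate when the absolute error of the
#'   model energy against the reference exceeds `E_T` but is at most
#'   `discard_multiplier * E_T`; errors beyond that mark structures too
#'   distorted to be informative and the candidate is discarded outright;
#' * the *similarity* selector adds a candidate when the maximum kernel
#'   similarity to the training set falls below `k_T`;
#' * the *distance* selector adds a candidate when its local outlier factor
#'   (LOF) in descriptor space exceeds the `percentile`-th percentile of the
#'   training set's own LOF values.
#'
#' @param E_T energy-error threshold (eV).
#' @param discard_multiplier factor on `E_T` beyond which candidates are
#'   discarded (default 10).
#' @param k_T similarity threshold in (0, 1]. A value of 1 is degenerate:
#'   every non-identical candidate is added and no extra information is
#'   gained.
#' @param zeta kernel exponent.
#' @param k neighbour count for LOF (>= 1).
#' @param percentile LOF threshold percentile (default 80).
#' @param min_initial_size smallest training set on which the distance
#'   selector is defined (>= k + 1).
#' @return a selector-config object.
#' @name selector_configs
NULL

#' @rdname selector_configs
#' @export
energy_selector_config <- function(E_T, discard_multiplier = 10) {
  if (!is.numeric(E_T) || E_T <= 0) stop("E_T must be positive")
  structure(list(E_T = E_T, discard_multiplier = discard_multiplier),
            class = "energy_selector_config")
}

#' @rdname selector_configs
#' @export
similarity_selector_config <- function(k_T = 0.9995, zeta = 4L) {
  if (!is.numeric(k_T) || k_T <= 0 || k_T > 1) stop("k_T must lie in (0, 1]")
  structure(list(k_T = k_T, zeta = as.integer(zeta)),
            class = "similarity_selector_config")
}

#' @rdname selector_configs
#' @export
distance_selector_config <- function(k = 10L, percentile = 80,
                                     min_initial_size = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  if (percentile <= 0 || percentile >= 100) stop("percentile must lie in (0, 100)")
  if (is.null(min_initial_size)) min_initial_size <- k + 1L
  min_initial_size <- as.integer(min_initial_size)
  if (min_initial_size < k + 1L) stop("min_initial_size must be >= k + 1")
  structure(list(k = k, percentile = percentile,
                 min_initial_size = min_initial_size),
            class = "distance_selector_config")
}

selector_decision <- function(verdict, score, threshold, selector) {
  structure(list(verdict = verdict, score = score, threshold_used = threshold,
                 selector = selector),
            class = "selector_decision")
}

#' @export
print.selector_decision <- function(x, ...) {
  cat(sprintf("<selector_decision> %s: %s (score %.6g, threshold %.6g)\n",
              x$selector, x$verdict, x$score, x$threshold_used))
  invisible(x)
}

#' Energy-threshold selector
#'
#' Partitions the absolute energy error into three contiguous intervals:
#' `[0, E_T]` -> skip, `(E_T, 10 E_T]` -> add, `(10 E_T, Inf)` -> discard.
#' This selector requires a ground-truth (reference) energy for every
#' evaluated candidate.
#'
#' @param E_ref reference (ground-truth) energy, eV.
#' @param E_mlp model-predicted energy, eV.
#' @param cfg an [energy_selector_config()].
#' @return a `selector_decision` with verdict add/skip/discard.
#' @export
energy_select <- function(E_ref, E_mlp, cfg) {
  stopifnot(inherits(cfg, "energy_selector_config"))
  if (is.null(E_ref) || is.na(E_ref)) {
    stop("energy selector requires a reference energy for the candidate")
  }
  err <- abs(E_ref - E_mlp)
  verdict <- if (err > cfg$discard_multiplier * cfg$E_T) "discard"
             else if (err > cfg$E_T) "add" else "skip"
  selector_decision(verdict, err, cfg$E_T, "energy")
}

#' Kernel-similarity selector
#'
#' Adds the candidate iff the maximum of its similarity vector against the
#' training descriptors falls below `k_T`.
#'
#' @param p_new candidate descriptor vector.
#' @param training list/matrix of training descriptor vectors.
#' @param cfg a [similarity_selector_config()].
#' @return a `selector_decision` (verdict add/skip, score = max similarity).
#' @export
similarity_select <- function(p_new, training, cfg) {
  stopifnot(inherits(cfg, "similarity_selector_config"))
  K <- similarity_vector(p_new, training, cfg$zeta)
  mx <- attr(K, "max")
  selector_decision(if (mx < cfg$k_T) "add" else "skip", mx, cfg$k_T,
                    "similarity")
}

#' Local outlier factor of a point against a dataset
#'
#' Computes, in descriptor space with Euclidean distances: the k-distance of
#' each neighbour (distance to its k-th nearest dataset neighbour, the
#' point itself excluded), reachability distances
#' `rd_k(o, a) = max(k-distance(a), d(o, a))`, the local reachability
#' density `lrd_k(o) = 1 / mean(rd_k(o, i))` over o's k nearest neighbours,
#' and `LOF_k(o)` as the mean ratio of neighbour lrd to own lrd. LOF close
#' to 1 means the point sits in a region as dense as its neighbours'; > 1
#' flags an outlier, < 1 an inlier.
#'
#' @param o query descriptor vector (need not be a dataset member; if it
#'   coincides with one, that member is excluded from its own neighbourhood).
#' @param dataset list/matrix of descriptor vectors, at least `k + 1` rows.
#' @param k neighbour count.
#' @return an object of class `lof_report` with fields `lof`, `lrd`,
#'   `neighbours`, `reach_dist`, `k_distance` (of the neighbours), `k`.
#' @export
lof_profile <- function(o, dataset, k = 10L) {
  M <- as_descriptor_matrix(dataset)
  k <- as.integer(k)
  n <- nrow(M)
  if (n < k + 1L) {
    stop("dataset too small for LOF: need at least min_initial_size = ",
         k + 1L, " points, got ", n)
  }
  if (anyDuplicated(M)) {
    stop("duplicate points in dataset give zero reachability density; ",
         "deduplicate the descriptor set before LOF")
  }
  o <- as.numeric(o)
  # distances of o to dataset and full pairwise dataset distances
  d_o <- sqrt(colSums((t(M) - o)^2))
  D <- as.matrix(stats::dist(M))
  # k-distance of every dataset point (ties broken by index order)
  kdist <- apply(D, 1L, function(row) sort(row[row > 0])[k])
  self <- which(d_o < 1e-12)
  cand <- setdiff(order(d_o), self)      # order() is stable: index ties
  nbrs <- cand[seq_len(k)]
  rd_o <- pmax(kdist[nbrs], d_o[nbrs])
  if (any(rd_o <= 0)) {
    stop("zero reachability distance (duplicate points); deduplicate first")
  }
  lrd_o <- 1 / mean(rd_o)
  # lrd of each neighbour, leave-self-out within the dataset
  lrd_nb <- vapply(nbrs, function(a) {
    da <- D[a, ]
    nb_a <- setdiff(order(da), a)[seq_len(k)]
    1 / mean(pmax(kdist[nb_a], da[nb_a]))
  }, numeric(1))
  lof <- mean(lrd_nb / lrd_o)
  structure(
    list(lof = lof, lrd = lrd_o, lrd_neighbours = lrd_nb, neighbours = nbrs,
         reach_dist = rd_o, k_distance = kdist[nbrs], k = k),
    class = "lof_report"
  )
}

#' @export
print.lof_report <- function(x, ...) {
  cat(sprintf("<lof_report> LOF_%d = %.6g (lrd %.6g)\n", x$k, x$lof, x$lrd))
  invisible(x)
}

#' LOF threshold of a training set
#'
#' The empirical `percentile`-th percentile (lower nearest-rank convention)
#' of leave-self-out LOF values over every training point. Recomputed
#' whenever the training set changes, so the outlier threshold tracks the
#' explored region of the potential-energy surface.
#'
#' @param training list/matrix of descriptor vectors.
#' @param k neighbour count.
#' @param percentile percentile in (0, 100); default 80.
#' @return scalar threshold, with attribute `lof_values`.
#' @export
lof_threshold <- function(training, k = 10L, percentile = 80) {
  M <- as_descriptor_matrix(training)
  n <- nrow(M)
  if (n < k + 1L) {
    stop("training set too small for LOF threshold: need min_initial_size = ",
         k + 1L, " points")
  }
  lofs <- vapply(seq_len(n), function(i) {
    lof_profile(M[i, ], M, k = k)$lof
  }, numeric(1))
  rank <- max(1L, ceiling(percentile / 100 * n))
  thr <- sort(lofs)[rank]
  attr(thr, "lof_values") <- lofs
  thr
}

#' LOF-based distance selector
#'
#' Adds the candidate iff its LOF against the training descriptors exceeds
#' the training set's own LOF percentile threshold. Requires a more
#' extensive initial training set than the other selectors since LOF needs
#' neighbourhood information.
#'
#' @param p_new candidate descriptor vector.
#' @param training list/matrix of training descriptor vectors.
#' @param cfg a [distance_selector_config()].
#' @return a `selector_decision` (verdict add/skip, score = LOF).
#' @export
distance_select <- function(p_new, training, cfg) {
  stopifnot(inherits(cfg, "distance_selector_config"))
  M <- as_descriptor_matrix(training)
  if (nrow(M) < cfg$min_initial_size) {
    stop("distance selector requires a training set of at least ",
         "min_initial_size = ", cfg$min_initial_size, " configurations ",
         "(got ", nrow(M), "); it relies on neighbouring information")
  }
  M <- M[!duplicated(M), , drop = FALSE]   # collapse exact duplicates
  thr <- lof_threshold(M, k = cfg$k, percentile = cfg$percentile)
  rep <- lof_profile(p_new, M, k = cfg$k)
  selector_decision(if (rep$lof > as.numeric(thr)) "add" else "skip",
                    rep$lof, as.numeric(thr), "distance")
}
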