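#' Reaction coordinate over two forming bonds
#'
#' `xi = (r1 + r2) / 2`, the mean of the two forming-bond distances; the
#' asynchronicity is `dr = |r2 - r1|`.
#'
#' @param pair1,pair2 atom-index pairs defining r1 and r2. The pairs may
#'   share atoms only when explicitly identical coordinates are wanted.
#' @return an object of class `reaction_coordinate`.
#' @export
reaction_coordinate <- function(pair1, pair2) {
  pair1 <- as.integer(pair1); pair2 <- as.integer(pair2)
  stopifnot(length(pair1) == 2L, length(pair2) == 2L)
  structure(list(pair1 = pair1, pair2 = pair2),
            class = "reaction_coordinate")
}

#' @rdname reaction_coordinate
#' @param rc a `reaction_coordinate`.
#' @param config a [configuration()].
#' @return `rc_distances()` returns `c(r1, r2)`; `rc_value()` returns xi.
#' @export
rc_distances <- function(rc, config) {
  p <- config$positions
  c(sqrt(sum((p[rc$pair1[1], ] - p[rc$pair1[2], ])^2)),
    sqrt(sum((p[rc$pair2[1], ] - p[rc$pair2[2], ])^2)))
}

#' @rdname reaction_coordinate
#' @export
rc_value <- function(rc, config) mean(rc_distances(rc, config))

rc_series <- function(rc, traj) {
  r1 <- traj_distance(traj, rc$pair1[1], rc$pair1[2])
  r2 <- traj_distance(traj, rc$pair2[1], rc$pair2[2])
  cbind(r1 = r1, r2 = r2)
}

#' Relaxed 2D scan over the two forming bonds
#'
#' For each `(r1, r2)` grid point the structure is minimized under stiff
#' harmonic restraints holding the forming bonds at their targets, warm
#' starting from the neighbouring grid point (snake traversal). Reported
#' energies are restraint-free energies at the relaxed geometries. A grid
#' point whose minimization does not converge is flagged and the scan
#' continues.
#'
#' @param potential a potential object.
#' @param start starting [configuration()].
#' @param rc a [reaction_coordinate()].
#' @param r1_grid,r2_grid monotone grids of bond-length targets (A).
#' @param restraint_k restraint spring (eV/A^2).
#' @param frozen_atoms indices kept fixed.
#' @param ftol convergence force tolerance (eV/A).
#' @return object of class `scan_2d`: list with `r1_grid`, `r2_grid`,
#'   `energies` (matrix, eV), `converged` (logical matrix).
#' @export
relaxed_scan_2d <- function(potential, start, rc, r1_grid, r2_grid,
                            restraint_k = 40, frozen_atoms = integer(0),
                            ftol = 1e-3) {
  if (is.unsorted(r1_grid) && is.unsorted(rev(r1_grid))) {
    stop("r1_grid must be monotone")
  }
  if (is.unsorted(r2_grid) && is.unsorted(rev(r2_grid))) {
    stop("r2_grid must be monotone")
  }
  n1 <- length(r1_grid); n2 <- length(r2_grid)
  E <- matrix(NA_real_, n1, n2)
  ok <- matrix(FALSE, n1, n2)
  row_start <- start
  for (i in seq_len(n1)) {
    cols <- if (i %% 2L == 1L) seq_len(n2) else rev(seq_len(n2))
    current <- row_start
    for (jj in seq_along(cols)) {
      j <- cols[jj]
      biases <- list(harmonic_bias(rc$pair1, restraint_k, r1_grid[i]),
                     harmonic_bias(rc$pair2, restraint_k, r2_grid[j]))
      res <- minimize_config(current, potential, biases = biases,
                             frozen_atoms = frozen_atoms, ftol = ftol)
      E[i, j] <- res$energy
      ok[i, j] <- res$converged
      current <- res$config
      if (jj == 1L) row_start <- res$config
    }
  }
  structure(list(r1_grid = r1_grid, r2_grid = r2_grid, energies = E,
                 converged = ok),
            class = "scan_2d")
}

#' Umbrella-sampling windows along the reaction coordinate
#'
#' Runs biased NVT MD per window: a steered warm start (each window begins
#' from the previous window's final frame), an equilibration burn-in (first
#' `burn_in` fraction of samples discarded) and production sampling of the
#' xi time series. Windows are checked for histogram overlap: a window
#' sharing no sampled xi range with any neighbouring window (by centre
#' order) is an error naming the gap.
#'
#' @param potential a potential object.
#' @param rc a [reaction_coordinate()].
#' @param window_spec data.frame with columns `center` (A) and `k`
#'   (eV/A^2); per-window spring overrides are plain rows.
#' @param md an [md_params()]; `duration` is the per-window production time.
#' @param start starting [configuration()] for the steer.
#' @param burn_in fraction of each window's samples discarded (default 0.1).
#' @param stride sampling stride (steps).
#' @return list of `umbrella_window` objects (fields `center`, `k`, `xi`,
#'   `temperature`).
#' @export
run_umbrella <- function(potential, rc, window_spec, md, start,
                         burn_in = 0.1, stride = 2L) {
  stopifnot(is.data.frame(window_spec),
            all(c("center", "k") %in% names(window_spec)))
  ord <- order(window_spec$center)
  dist0 <- abs(rc_value(rc, start) - window_spec$center)
  if (which.min(dist0) %in% utils::tail(ord, 1L)) ord <- rev(ord)
  windows <- vector("list", nrow(window_spec))
  current <- start
  for (w in ord) {
    ctr <- window_spec$center[w]; kk <- window_spec$k[w]
    bias <- harmonic_bias(c(rc$pair1, rc$pair2), kk, ctr)
    prm <- md
    prm$rng_seed <- md$rng_seed + w
    traj <- run_md(current, potential, prm, biases = list(bias),
                   stride = stride)
    if (traj$unstable) stop("window at ", ctr, " A became unstable")
    xi <- as.numeric(traj$bias_values[, 1])
    keep <- xi[-seq_len(max(1L, floor(burn_in * length(xi))))]
    windows[[w]] <- structure(
      list(center = ctr, k = kk, xi = keep, temperature = md$temperature),
      class = "umbrella_window")
    current <- traj$final
  }
  check_window_overlap(windows)
  windows
}

check_window_overlap <- function(windows) {
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  rngs <- lapply(windows, function(w) range(w$xi))
  for (i in seq_along(ord)) {
    nb <- c(if (i > 1L) ord[i - 1L], if (i < length(ord)) ord[i + 1L])
    w <- ord[i]
    overlaps <- vapply(nb, function(j) {
      rngs[[w]][1] <= rngs[[j]][2] && rngs[[j]][1] <= rngs[[w]][2]
    }, logical(1))
    if (length(overlaps) && !any(overlaps)) {
      stop("umbrella window at ", windows[[w]]$center,
           " A has zero histogram overlap with its neighbours; ",
           "add windows or increase sampling")
    }
  }
  invisible(TRUE)
}

#' Reconstruct a free-energy profile by WHAM
#'
#' Weighted-histogram self-consistent iteration over the biased windows to
#' tolerance `tol` on the window free-energy constants. The profile is
#' min-shifted to 0 and reported in kcal/mol; the activation free energy is
#' the difference between the highest interior maximum separating the two
#' outermost basins and the reactant-side basin minimum.
#'
#' @param windows list of umbrella windows from [run_umbrella()].
#' @param n_bins histogram bins over the sampled xi range.
#' @param tol convergence tolerance (eV) on window free energies.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @param reactant_side `"high"` if the reactant basin lies at large xi
#'   (bond formation), `"low"` otherwise.
#' @return object of class `fes_result`: `xi` (bin centres), `free_energy`
#'   (kcal/mol, min 0), `barrier` (kcal/mol), `basins`, `ts_xi`.
#' @export
reconstruct_fes <- function(windows, n_bins = 200L, tol = 1e-7,
                            max_iter = 50000L, reactant_side = c("high", "low")) {
  reactant_side <- match.arg(reactant_side)
  temps <- vapply(windows, `[[`, numeric(1), "temperature")
  if (diff(range(temps)) > 1e-9) stop("windows disagree on temperature")
  beta <- 1 / (KB_EV * temps[1])
  allxi <- unlist(lapply(windows, `[[`, "xi"))
  edges <- seq(min(allxi), max(allxi), length.out = n_bins + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  W <- length(windows)
  counts <- matrix(0, W, n_bins)
  Nw <- numeric(W)
  for (w in seq_len(W)) {
    h <- findInterval(windows[[w]]$xi, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
    counts[w, ] <- tabulate(h, n_bins)
    Nw[w] <- length(windows[[w]]$xi)
  }
  # bias energy of window w at bin centre b
  Ub <- t(vapply(windows, function(wd) 0.5 * wd$k * (mids - wd$center)^2,
                 numeric(n_bins)))
  expU <- exp(-beta * Ub)
  f <- numeric(W)
  total <- colSums(counts)
  for (it in seq_len(max_iter)) {
    denom <- colSums(Nw * exp(beta * f) * expU)
    P <- ifelse(denom > 0, total / denom, 0)
    fnew <- -log(colSums(t(expU) * P)) / beta
    fnew <- fnew - fnew[1]
    resid <- max(abs(fnew - f))
    f <- fnew
    if (resid < tol) break
    if (it == max_iter) {
      stop("WHAM did not converge in ", max_iter,
           " iterations (residual ", format(resid), " eV)")
    }
  }
  occupied <- total > 0
  Fv <- rep(NA_real_, n_bins)
  Fv[occupied] <- -log(P[occupied]) / beta
  Fv <- Fv - min(Fv, na.rm = TRUE)
  Fk <- Fv * EV_TO_KCAL_MOL
  prof <- profile_features(mids[occupied], Fk[occupied], reactant_side)
  structure(
    list(xi = mids, free_energy = Fk, barrier = prof$barrier,
         basins = prof$basins, ts_xi = prof$ts_xi, iterations = it,
         window_free_energies = f),
    class = "fes_result"
  )
}

# locate basins and the separating maximum of a 1D profile
profile_features <- function(x, F, reactant_side) {
  n <- length(F)
  if (n < 5L) return(list(barrier = NA_real_, basins = NA, ts_xi = NA_real_))
  # light smoothing to suppress single-bin noise in extremum detection
  Fs <- stats::filter(F, rep(1 / 5, 5), sides = 2)
  Fs[is.na(Fs)] <- F[is.na(Fs)]
  is_min <- c(FALSE, diff(sign(diff(Fs))) > 0, FALSE)
  minima <- which(is_min)
  ends <- c(1L, n)
  basins <- sort(unique(c(minima,
                          ends[vapply(ends, function(e)
                            Fs[e] < Fs[ifelse(e == 1L, min(e + 3L, n),
                                              max(e - 3L, 1L))],
                            logical(1))])))
  if (length(basins) < 2L) {
    return(list(barrier = NA_real_, basins = x[basins], ts_xi = NA_real_))
  }
  lo <- min(basins); hi <- max(basins)
  inner <- seq(lo, hi)
  ts_idx <- inner[which.max(Fs[inner])]
  reactant_idx <- if (reactant_side == "high") hi else lo
  barrier <- F[ts_idx] - F[reactant_idx]
  list(barrier = barrier, basins = x[basins], ts_xi = x[ts_idx])
}

#' @export
print.fes_result <- function(x, ...) {
  cat(sprintf("<fes_result> %d bins, barrier %.3f kcal/mol at xi = %.3f A\n",
              length(x$xi), x$barrier, x$ts_xi))
  invisible(x)
}

#' Write a free-energy profile as two-column text
#'
#' @param fes a `fes_result`.
#' @param path destination (columns: xi in A, F in kcal/mol).
#' @export
write_fes <- function(fes, path) {
  utils::write.table(data.frame(xi = fes$xi, free_energy = fes$free_energy),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify the reactive state from the two forming-bond distances
#'
#' Product when both distances are below `product_max` (1.6 A); reactant
#' when both exceed `reactant_min` (3.0 A); otherwise ongoing.
#'
#' @param r1,r2 forming-bond distances (A), scalars or vectors.
#' @param product_max,reactant_min thresholds (A).
#' @return character vector: `"product"`, `"reactant"` or `"ongoing"`.
#' @export
classify_state <- function(r1, r2, product_max = 1.6, reactant_min = 3.0) {
  if (any(c(r1, r2) <= 0)) stop("distances must be positive")
  ifelse(r1 < product_max & r2 < product_max, "product",
         ifelse(r1 > reactant_min & r2 > reactant_min, "reactant", "ongoing"))
}

first_crossing_below <- function(r, times, threshold) {
  idx <- which(r < threshold)
  if (!length(idx)) return(NA_real_)
  times[idx[1]]
}

analyze_reactive_traj <- function(traj, rc, product_max = 1.6,
                                  reactant_min = 3.0, gap_criterion = 60) {
  rr <- rc_series(rc, traj)
  states <- classify_state(rr[, 1], rr[, 2], product_max, reactant_min)
  terminal_idx <- which(states != "ongoing")[1]
  outcome <- if (is.na(terminal_idx)) "timeout" else states[terminal_idx]
  t1 <- first_crossing_below(rr[, 1], traj$times, product_max)
  t2 <- first_crossing_below(rr[, 2], traj$times, product_max)
  gap <- if (!is.na(t1) && !is.na(t2)) abs(t2 - t1) else NA_real_
  list(outcome = outcome,
       terminal_time = if (is.na(terminal_idx)) NA_real_ else traj$times[terminal_idx],
       t_r1 = t1, t_r2 = t2, time_gap = gap,
       concerted = if (is.na(gap)) NA else gap < gap_criterion,
       r_final = rr[nrow(rr), ])
}

#' Downhill trajectory ensemble from a transition-state pool
#'
#' Unbiased NVE trajectories launched from each (solvent-adapted,
#' restrained-optimized) transition-state structure with fresh
#' Maxwell-Boltzmann velocities, propagated until product or reactant forms
#' or `max_time` elapses. Per trajectory: terminal classification,
#' bond-formation times (first downward crossing of the product threshold
#' per bond), and the formation time gap; trajectories that neither commit
#' are `timeout` and excluded from gap statistics. The ensemble summary
#' reports the mean time gap and the fraction of concerted trajectories
#' under the `gap_criterion` (60 fs separates concerted from stepwise).
#'
#' @param ts_pool a [configuration_set()] of transition-state structures
#'   (see [prepare_ts_pool()]).
#' @param potential a potential object.
#' @param rc a [reaction_coordinate()].
#' @param md an [md_params()] (its `duration` is ignored; `max_time` rules).
#' @param max_time per-trajectory cap (fs; default 2000).
#' @param gap_criterion concerted/stepwise threshold (fs).
#' @param product_max,reactant_min state thresholds (A).
#' @return object of class `downhill_result`: `outcomes` data.frame (one
#'   row per trajectory) and `summary` list (`mean_gap`,
#'   `fraction_concerted`, counts).
#' @export
downhill_ensemble <- function(ts_pool, potential, rc, md, max_time = 2000,
                              gap_criterion = 60, product_max = 1.6,
                              reactant_min = 3.0) {
  rows <- list()
  for (i in seq_len(length(ts_pool))) {
    prm <- md
    prm$ensemble <- "nve"; prm$friction <- 0
    prm$duration <- max_time
    prm$rng_seed <- md$rng_seed + i
    traj <- run_md(ts_pool[[i]], potential, prm, stride = 1L)
    an <- analyze_reactive_traj(traj, rc, product_max, reactant_min,
                                gap_criterion)
    rows[[i]] <- data.frame(
      trajectory = i, outcome = an$outcome, terminal_time = an$terminal_time,
      t_r1 = an$t_r1, t_r2 = an$t_r2, time_gap = an$time_gap,
      concerted = an$concerted)
  }
  outcomes <- do.call(rbind, rows)
  formed <- outcomes[outcomes$outcome == "product" & !is.na(outcomes$time_gap), ]
  structure(
    list(outcomes = outcomes,
         summary = list(
           mean_gap = if (nrow(formed)) mean(formed$time_gap) else NA_real_,
           fraction_concerted = if (nrow(formed)) mean(formed$concerted) else NA_real_,
           n_product = sum(outcomes$outcome == "product"),
           n_reactant = sum(outcomes$outcome == "reactant"),
           n_timeout = sum(outcomes$outcome == "timeout"))),
    class = "downhill_result"
  )
}

#' Prepare a solvent-adapted transition-state pool
#'
#' Equilibrates the solvent around a fixed solute in the NVT ensemble,
#' collects snapshots at a fixed interval, and restrained-optimizes each
#' snapshot (solvent fixed, harmonic restraints holding the forming bonds
#' at their transition-state distances).
#'
#' @param ts_config a [configuration()] at/near the transition state.
#' @param potential a potential object.
#' @param rc a [reaction_coordinate()].
#' @param solute_atoms indices of the solute.
#' @param md an [md_params()] for the equilibration.
#' @param n_snapshots number of pool members.
#' @param snapshot_interval time between snapshots (fs).
#' @param restraint_k spring holding r1/r2 at their start values (eV/A^2).
#' @return a [configuration_set()] of optimized transition states.
#' @export
prepare_ts_pool <- function(ts_config, potential, rc, solute_atoms, md,
                            n_snapshots = 4L, snapshot_interval = 500,
                            restraint_k = 20) {
  r_ts <- rc_distances(rc, ts_config)
  solvent_atoms <- setdiff(seq_len(n_atoms(ts_config)), solute_atoms)
  pool <- list()
  current <- ts_config
  for (s in seq_len(n_snapshots)) {
    if (length(solvent_atoms)) {
      prm <- md
      prm$duration <- snapshot_interval
      prm$rng_seed <- md$rng_seed + s
      traj <- run_md(current, potential, prm, frozen_atoms = solute_atoms,
                     stride = max(1L, as.integer(snapshot_interval / md$dt)))
      current <- traj$final
    }
    biases <- list(harmonic_bias(rc$pair1, restraint_k, r_ts[1]),
                   harmonic_bias(rc$pair2, restraint_k, r_ts[2]))
    opt <- minimize_config(current, potential, biases = biases,
                           frozen_atoms = solvent_atoms)
    cf <- opt$config
    cf$provenance$ts_snapshot <- s
    pool[[s]] <- cf
  }
  configuration_set(pool, name = "ts_pool")
}

#' Prepare a reactant-state pool by restrained equilibration
#'
#' Equilibrates the reactant with the two forming bonds held by harmonic
#' restraints; the restraint centres must lie in the reactant range
#' `[3.0, 5.0]` A.
#'
#' @param start a reactant-side [configuration()].
#' @param potential a potential object.
#' @param rc a [reaction_coordinate()].
#' @param restraint_centers length-2 vector of r1/r2 restraint centres (A).
#' @param restraint_k spring (eV/A^2).
#' @param md an [md_params()].
#' @param n_snapshots pool size.
#' @param snapshot_interval time between snapshots (fs).
#' @return a [configuration_set()].
#' @export
prepare_rs_pool <- function(start, potential, rc,
                            restraint_centers = c(3.5, 3.5), restraint_k = 2,
                            md = md_params(), n_snapshots = 4L,
                            snapshot_interval = 500) {
  if (any(restraint_centers < 3.0) || any(restraint_centers > 5.0)) {
    stop("reactant-state restraint centres must lie in [3.0, 5.0] A")
  }
  biases <- list(harmonic_bias(rc$pair1, restraint_k, restraint_centers[1]),
                 harmonic_bias(rc$pair2, restraint_k, restraint_centers[2]))
  pool <- list()
  current <- start
  for (s in seq_len(n_snapshots)) {
    prm <- md
    prm$duration <- snapshot_interval
    prm$rng_seed <- md$rng_seed + 100L + s
    traj <- run_md(current, potential, prm, biases = biases,
                   stride = max(1L, as.integer(snapshot_interval / md$dt)))
    current <- traj$final
    cf <- current
    cf$provenance$rs_snapshot <- s
    pool[[s]] <- cf
  }
  configuration_set(pool, name = "rs_pool")
}

#' Uphill trajectory ensemble from the reactant state
#'
#' Biased trajectories launched from reactant-state structures with a
#' harmonic driving potential on the reaction coordinate (default spring
#' 0.4 eV/A^2) pulling xi toward the product value, propagated until
#' product forms or `max_time` (default 3 ps) elapses. In contrast to
#' downhill dynamics the solvent has time to reorganise before the barrier
#' is crossed. Per-frame xi is logged for reactant/intermediate/product
#' analyses.
#'
#' @param rs_pool a [configuration_set()] from [prepare_rs_pool()].
#' @param potential a potential object.
#' @param rc a [reaction_coordinate()].
#' @param md an [md_params()].
#' @param bias_k driving spring constant (eV/A^2).
#' @param target_xi bias centre (A), the product-side xi.
#' @param max_time per-trajectory cap (fs).
#' @param product_max product threshold (A).
#' @return object of class `uphill_result`: `outcomes` data.frame and the
#'   per-trajectory xi series in `xi_series`.
#' @export
uphill_ensemble <- function(rs_pool, potential, rc, md, bias_k = 0.4,
                            target_xi = 1.55, max_time = 3000,
                            product_max = 1.6) {
  rows <- list(); series <- list()
  for (i in seq_len(length(rs_pool))) {
    prm <- md
    prm$duration <- max_time
    prm$rng_seed <- md$rng_seed + i
    bias <- harmonic_bias(c(rc$pair1, rc$pair2), bias_k, target_xi)
    traj <- run_md(rs_pool[[i]], potential, prm, biases = list(bias),
                   stride = 1L)
    rr <- rc_series(rc, traj)
    prod_idx <- which(rr[, 1] < product_max & rr[, 2] < product_max)[1]
    rows[[i]] <- data.frame(
      trajectory = i,
      outcome = if (is.na(prod_idx)) "timeout" else "product",
      t_product = if (is.na(prod_idx)) NA_real_ else traj$times[prod_idx])
    series[[i]] <- data.frame(time = traj$times, xi = (rr[, 1] + rr[, 2]) / 2,
                              r1 = rr[, 1], r2 = rr[, 2])
  }
  structure(list(outcomes = do.call(rbind, rows), xi_series = series),
            class = "uphill_result")
}

#' Radial distribution function
#'
#' Pair-distance histogram between two species over a periodic trajectory,
#' normalized by the ideal-gas density so g(r) tends to 1 in a homogeneous
#' fluid; distances use the minimum-image convention.
#'
#' @param traj a `trajectory` with a shared periodic cell.
#' @param species_pair character length-2, e.g. `c("O", "O")`.
#' @param r_max histogram range (A); must not exceed half the shortest box
#'   vector.
#' @param n_bins number of bins.
#' @param frames optional frame subset.
#' @return data.frame with columns `r` (bin centres) and `g`.
#' @export
rdf <- function(traj, species_pair = c("O", "O"), r_max = NULL,
                n_bins = 100L, frames = NULL) {
  if (!traj$periodic || is.null(traj$cell)) {
    stop("rdf requires a periodic trajectory with a cell")
  }
  L <- min(sqrt(rowSums(traj$cell^2)))
  if (is.null(r_max)) r_max <- L / 2
  if (r_max > L / 2 + 1e-9) {
    stop("r_max (", r_max, " A) exceeds half the shortest box length (",
         L / 2, " A)")
  }
  if (is.null(frames)) frames <- seq_len(traj_n_frames(traj))
  ia <- which(traj$species == species_pair[1])
  ib <- which(traj$species == species_pair[2])
  if (!length(ia) || !length(ib)) stop("species not present in trajectory")
  V <- abs(det(traj$cell))
  inv <- solve(traj$cell)
  edges <- seq(0, r_max, length.out = n_bins + 1L)
  counts <- numeric(n_bins)
  same <- identical(species_pair[1], species_pair[2])
  for (f in frames) {
    fr_pos <- matrix(traj$positions[, , f], ncol = 3L)
    pa <- fr_pos[ia, , drop = FALSE]
    pb <- fr_pos[ib, , drop = FALSE]
    for (q in seq_along(ia)) {
      dv <- sweep(pb, 2L, pa[q, ])
      fr <- dv %*% inv; fr <- fr - round(fr)
      dv <- fr %*% traj$cell
      r <- sqrt(rowSums(dv^2))
      if (same) r <- r[-q]
      r <- r[r < r_max & r > 1e-8]
      counts <- counts + tabulate(findInterval(r, edges,
                                               rightmost.closed = TRUE),
                                  n_bins)
    }
  }
  nf <- length(frames)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  nb_eff <- if (same) length(ib) - 1L else length(ib)
  ideal <- shell * nb_eff / V
  g <- counts / (nf * length(ia)) / ideal
  data.frame(r = (edges[-1] + edges[-length(edges)]) / 2, g = g)
}

#' Hydrogen-bond criterion
#'
#' Standard geometric definition: donor-acceptor heavy-atom distance below
#' `dist_cut` and donor-H-acceptor angle above `angle_cut`.
#'
#' @param dist_cut donor-acceptor O..O distance cutoff (A).
#' @param angle_cut donor-H-acceptor angle cutoff (degrees, in (90, 180]).
#' @return an object of class `hb_criterion`.
#' @export
hb_criterion <- function(dist_cut = 3.5, angle_cut = 140) {
  if (dist_cut <= 0) stop("dist_cut must be positive")
  if (angle_cut <= 90 || angle_cut > 180) stop("angle_cut must lie in (90, 180]")
  structure(list(dist_cut = dist_cut, angle_cut = angle_cut),
            class = "hb_criterion")
}

#' Find hydrogen bonds in a configuration
#'
#' O-H donors are detected by molecular connectivity; an H-bond is counted
#' between a donor O-H and an acceptor O of a different molecule when the
#' criterion holds.
#'
#' @param config a [configuration()].
#' @param criterion an [hb_criterion()].
#' @return data.frame with columns `donor_o`, `h`, `acceptor_o`, `dist`,
#'   `angle`.
#' @export
find_hbonds <- function(config, criterion = hb_criterion()) {
  mol <- molecule_ids(config)
  os <- which(config$species == "O")
  hs <- which(config$species == "H")
  pos <- config$positions
  # assign each H to its bonded O (same molecule, nearest)
  rows <- list()
  for (h in hs) {
    cand <- os[mol[os] == mol[h]]
    if (!length(cand)) next
    d <- sqrt(colSums((t(pos[cand, , drop = FALSE]) - pos[h, ])^2))
    od <- cand[which.min(d)]
    for (oa in os[mol[os] != mol[h]]) {
      dv <- pos[oa, ] - pos[od, ]
      doo <- sqrt(sum(dv^2))
      if (doo >= criterion$dist_cut) next
      v1 <- pos[od, ] - pos[h, ]
      v2 <- pos[oa, ] - pos[h, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      if (ang > criterion$angle_cut) {
        rows[[length(rows) + 1L]] <- data.frame(
          donor_o = od, h = h, acceptor_o = oa, dist = doo, angle = ang)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(donor_o = integer(0), h = integer(0),
                      acceptor_o = integer(0), dist = numeric(0),
                      angle = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Hydrogen bonds per solvent molecule versus distance from the solute
#'
#' For every frame, counts the hydrogen bonds each solvent molecule
#' participates in (as donor or acceptor) and bins the per-molecule counts
#' by the distance of the molecule's oxygen from the centre of mass of the
#' solute atoms. The far-field bin estimates the bulk value. Bins with no
#' molecules are reported as `NA`, not zero.
#'
#' @param traj a `trajectory`.
#' @param criterion an [hb_criterion()].
#' @param solute_atoms indices of the solute (excluded from the solvent
#'   statistics); may be empty for a pure-solvent box, in which case the
#'   distance is measured from the centre of mass of everything.
#' @param shell_bins numeric vector of bin edges (A).
#' @param frames optional frame subset.
#' @return data.frame: `d_lo`, `d_hi`, `mean_hbs`, `n_obs`.
#' @export
count_hbs_by_distance <- function(traj, criterion = hb_criterion(),
                                  solute_atoms = integer(0),
                                  shell_bins = seq(0, 10, by = 1),
                                  frames = NULL) {
  if (is.null(frames)) frames <- seq_len(traj_n_frames(traj))
  sums <- numeric(length(shell_bins) - 1L)
  nobs <- numeric(length(shell_bins) - 1L)
  for (f in frames) {
    cf <- traj_frame(traj, f)
    mol <- molecule_ids(cf)
    hb <- find_hbonds(cf, criterion)
    masses <- atomic_masses(cf$species)
    ref_atoms <- if (length(solute_atoms)) solute_atoms else seq_len(n_atoms(cf))
    com <- colSums(cf$positions[ref_atoms, , drop = FALSE] *
                     masses[ref_atoms]) / sum(masses[ref_atoms])
    solute_mols <- if (length(solute_atoms)) unique(mol[solute_atoms]) else integer(0)
    for (m in setdiff(unique(mol), solute_mols)) {
      idx <- which(mol == m)
      o <- idx[cf$species[idx] == "O"]
      if (!length(o)) next
      nhb <- sum(mol[hb$donor_o] == m | mol[hb$acceptor_o] == m)
      d <- sqrt(sum((cf$positions[o[1], ] - com)^2))
      b <- findInterval(d, shell_bins)
      if (b >= 1L && b <= length(sums)) {
        sums[b] <- sums[b] + nhb
        nobs[b] <- nobs[b] + 1L
      }
    }
  }
  data.frame(
    d_lo = shell_bins[-length(shell_bins)], d_hi = shell_bins[-1],
    mean_hbs = ifelse(nobs > 0, sums / nobs, NA_real_), n_obs = nobs)
}
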