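#' MD run parameters
#'
#' @param dt timestep (fs); 0.5 fs is the default used throughout the
#'   active-learning episodes.
#' @param temperature target temperature (K).
#' @param ensemble `"nve"` or `"nvt"` (Langevin thermostat).
#' @param friction Langevin friction (1/fs); only used for NVT.
#' @param duration total simulated time (fs); must be a multiple of `dt`.
#' @param rng_seed integer seed for velocity initialization and thermostat
#'   noise; fixed seed makes runs bit-reproducible.
#' @return an object of class `md_params`.
#' @export
md_params <- function(dt = 0.5, temperature = 300, ensemble = c("nvt", "nve"),
                      friction = 0.02, duration = 1000, rng_seed = 1L) {
  ensemble <- match.arg(ensemble)
  if (dt <= 0) stop("dt must be positive")
  if (temperature < 0) stop("temperature must be >= 0")
  nsteps <- duration / dt
  if (abs(nsteps - round(nsteps)) > 1e-9) {
    stop("duration (", duration, " fs) must be a multiple of dt (", dt, " fs)")
  }
  structure(list(dt = dt, temperature = temperature, ensemble = ensemble,
                 friction = if (ensemble == "nvt") friction else 0,
                 duration = duration, rng_seed = as.integer(rng_seed)),
            class = "md_params")
}

#' Harmonic bias on a distance or reaction coordinate
#'
#' Bias energy `0.5 k (xi - center)^2` with its exact negative gradient
#' added to the forces; `xi` is either one interatomic distance (2 atom
#' indices) or the two-bond reaction coordinate `(r1 + r2) / 2` (4 atom
#' indices, see [reaction_coordinate()]).
#'
#' @param atoms integer vector of 2 (distance) or 4 (reaction coordinate)
#'   atom indices.
#' @param k spring constant (eV/A^2).
#' @param center bias centre (A).
#' @return an object of class `harmonic_bias`.
#' @export
harmonic_bias <- function(atoms, k, center) {
  atoms <- as.integer(atoms)
  if (!length(atoms) %in% c(2L, 4L)) stop("atoms must have length 2 or 4")
  if (k < 0) stop("spring constant must be >= 0")
  structure(list(type = if (length(atoms) == 2L) "distance" else "rcoord",
                 atoms = atoms, k = k, center = center),
            class = "harmonic_bias")
}

#' Maxwell-Boltzmann velocity initialization
#'
#' Per-atom Gaussian velocities at the target temperature with the net
#' linear momentum removed; `temperature = 0` gives all-zero velocities.
#'
#' @param config a [configuration()].
#' @param temperature kelvin.
#' @param rng_seed integer seed.
#' @return n x 3 matrix of velocities (A/fs).
#' @export
init_velocities <- function(config, temperature, rng_seed = 1L) {
  if (temperature < 0) stop("temperature must be >= 0")
  n <- n_atoms(config)
  if (temperature == 0) return(matrix(0, n, 3L))
  m <- atomic_masses(config$species)
  v <- withr_seed(rng_seed, {
    sd <- sqrt(KB_EV * temperature / (m * AMU_A2_FS2_TO_EV))
    matrix(stats::rnorm(3L * n), n, 3L) * sd
  })
  # remove centre-of-mass momentum
  p <- colSums(v * m)
  sweep(v, 2L, p / sum(m))
}

#' Run molecular dynamics
#'
#' Velocity-Verlet integration (BAOAB splitting with a Langevin
#' Ornstein-Uhlenbeck step for NVT). Harmonic biases are added to the
#' potential energy and forces at every step; frozen atoms are excluded
#' from integration and keep their coordinates exactly. A non-finite force
#' or any force component beyond `fmax_abort` aborts the run and returns
#' the partial trajectory flagged `unstable` - the stability signal used by
#' active learning.
#'
#' @param config starting [configuration()].
#' @param potential a potential object (see [evaluate()]).
#' @param params an [md_params()].
#' @param biases list of [harmonic_bias()] objects.
#' @param frozen_atoms integer indices of atoms to freeze.
#' @param stride record every `stride`-th step (the initial frame is always
#'   recorded).
#' @param velocities optional starting velocities; default Maxwell-Boltzmann
#'   at `params$temperature` with seed `params$rng_seed`.
#' @param fmax_abort instability threshold (eV/A).
#' @return an object of class `trajectory`.
#' @export
run_md <- function(config, potential, params, biases = list(),
                   frozen_atoms = integer(0), stride = 1L,
                   velocities = NULL, fmax_abort = 1e3) {
  stopifnot(inherits(config, "configuration"), inherits(params, "md_params"))
  if (inherits(biases, "harmonic_bias")) biases <- list(biases)
  n <- n_atoms(config)
  frozen <- rep(FALSE, n)
  frozen[as.integer(frozen_atoms)] <- TRUE
  if (is.null(velocities)) {
    velocities <- init_velocities(config, params$temperature, params$rng_seed)
  }
  velocities[frozen, ] <- 0
  nsteps <- as.integer(round(params$duration / params$dt))
  mass <- atomic_masses(config$species)
  biaslist <- lapply(biases, unclass)

  if (inherits(potential, "r_function_potential")) {
    res <- md_run_r(config, potential, biaslist, velocities, mass, frozen,
                    params, nsteps, stride, fmax_abort)
  } else {
    species_tab <- unique(config$species)
    potspec <- if (inherits(potential, "soap_krr_mlp")) {
      species_tab <- potential$soap$species
      as_potspec(potential)
    } else {
      as_potspec(potential, config)
    }
    codes <- match(config$species, species_tab) - 1L
    if (anyNA(codes)) stop("unsupported species for this potential")
    res <- withr_seed(params$rng_seed + 104729L, {
      md_run_cpp(config$positions, velocities, mass, as.integer(codes),
                 potspec, biaslist, frozen, params$dt, nsteps,
                 params$friction, params$temperature, as.integer(stride),
                 if (is.null(config$cell)) NULL else config$cell,
                 config$periodic, fmax_abort)
    })
  }

  structure(
    list(positions = res$positions, times = res$times, epot = res$epot,
         ekin = res$ekin, bias_values = res$bias_values,
         species = config$species, cell = config$cell,
         periodic = config$periodic, dt = params$dt,
         n_biases = length(biases),
         final = configuration(config$species, res$final_positions,
                               cell = config$cell, periodic = config$periodic,
                               provenance = config$provenance),
         final_velocities = res$final_velocities,
         unstable = isTRUE(res$unstable), steps_done = res$steps_done,
         frozen = which(frozen)),
    class = "trajectory"
  )
}

# Pure-R fallback integrator for R-function potentials (same BAOAB scheme).
md_run_r <- function(config, potential, biaslist, vel, mass, frozen, params,
                     nsteps, stride, fmax_abort) {
  x <- config$positions
  n <- nrow(x)
  free <- !frozen
  dt <- params$dt
  c1 <- if (params$friction > 0) exp(-params$friction * dt) else 1
  eval_all <- function(pos) {
    cf <- configuration(config$species, pos, config$cell, config$periodic)
    res <- evaluate(potential, cf, forces = TRUE)
    bvals <- numeric(length(biaslist))
    for (bi in seq_along(biaslist)) {
      b <- biaslist[[bi]]
      bb <- bias_eval_r(b, pos)
      res$energy <- res$energy + bb$energy
      res$forces <- res$forces + bb$forces
      bvals[bi] <- bb$value
    }
    c(res, list(bias = bvals))
  }
  kin <- function(v) sum(0.5 * mass * rowSums(v^2)) * AMU_A2_FS2_TO_EV
  bad <- function(F) any(!is.finite(F)) || max(abs(F)) > fmax_abort
  nf <- nsteps %/% stride + 1L
  posrec <- array(NA_real_, c(n, 3L, nf))
  times <- epot <- ekin <- numeric(nf)
  bias_values <- matrix(0, nf, max(1L, length(biaslist)))
  ev <- eval_all(x)
  unstable <- bad(ev$forces)
  rec <- 0L
  record <- function(t) {
    rec <<- rec + 1L
    posrec[, , rec] <<- x
    times[rec] <<- t; epot[rec] <<- ev$energy; ekin[rec] <<- kin(vel)
    if (length(biaslist)) bias_values[rec, ] <<- ev$bias
  }
  record(0)
  steps_done <- 0L
  if (!unstable) {
    withr_seed(params$rng_seed + 104729L, {
      for (step in seq_len(nsteps)) {
        vel[free, ] <- vel[free, ] + 0.5 * dt * EVA_AMU_ACC *
          ev$forces[free, , drop = FALSE] / mass[free]
        x[free, ] <- x[free, ] + 0.5 * dt * vel[free, , drop = FALSE]
        if (params$friction > 0) {
          c2 <- sqrt((1 - c1^2) * KB_EV * params$temperature /
                       (mass[free] * AMU_A2_FS2_TO_EV))
          vel[free, ] <- c1 * vel[free, , drop = FALSE] +
            c2 * matrix(stats::rnorm(3 * sum(free)), ncol = 3L)
        }
        x[free, ] <- x[free, ] + 0.5 * dt * vel[free, , drop = FALSE]
        ev <- eval_all(x)
        if (bad(ev$forces)) {
          unstable <- TRUE; steps_done <- step; record(step * dt); break
        }
        vel[free, ] <- vel[free, ] + 0.5 * dt * EVA_AMU_ACC *
          ev$forces[free, , drop = FALSE] / mass[free]
        steps_done <- step
        if (step %% stride == 0L) record(step * dt)
      }
    })
  }
  list(positions = posrec[, , seq_len(rec), drop = FALSE],
       times = times[seq_len(rec)], epot = epot[seq_len(rec)],
       ekin = ekin[seq_len(rec)],
       bias_values = bias_values[seq_len(rec), , drop = FALSE],
       final_positions = x, final_velocities = vel, unstable = unstable,
       steps_done = steps_done)
}

bias_eval_r <- function(b, pos) {
  F <- matrix(0, nrow(pos), 3L)
  if (b$type == "distance") {
    i <- b$atoms[1]; j <- b$atoms[2]
    dv <- pos[j, ] - pos[i, ]
    r <- sqrt(sum(dv^2))
    dEdr <- b$k * (r - b$center)
    F[j, ] <- -dEdr * dv / r
    F[i, ] <- dEdr * dv / r
    list(energy = 0.5 * b$k * (r - b$center)^2, forces = F, value = r)
  } else {
    i1 <- b$atoms[1]; j1 <- b$atoms[2]; i2 <- b$atoms[3]; j2 <- b$atoms[4]
    d1 <- pos[j1, ] - pos[i1, ]; r1 <- sqrt(sum(d1^2))
    d2 <- pos[j2, ] - pos[i2, ]; r2 <- sqrt(sum(d2^2))
    xi <- (r1 + r2) / 2
    dEdxi <- b$k * (xi - b$center)
    F[j1, ] <- F[j1, ] - 0.5 * dEdxi * d1 / r1
    F[i1, ] <- F[i1, ] + 0.5 * dEdxi * d1 / r1
    F[j2, ] <- F[j2, ] - 0.5 * dEdxi * d2 / r2
    F[i2, ] <- F[i2, ] + 0.5 * dEdxi * d2 / r2
    list(energy = 0.5 * b$k * (xi - b$center)^2, forces = F, value = xi)
  }
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", traj_n_frames(x), " frames, ", length(x$species),
      " atoms, ", max(x$times), " fs",
      if (x$unstable) " [UNSTABLE]" else "", "\n", sep = "")
  invisible(x)
}

#' Trajectory accessors
#'
#' @param traj a `trajectory` from [run_md()].
#' @param i frame index.
#' @return `traj_frame()` a [configuration()]; `traj_n_frames()` the frame
#'   count; `traj_temperature()` instantaneous kinetic temperatures (K);
#'   `traj_distance()` the time series of one interatomic distance.
#' @export
traj_n_frames <- function(traj) dim(traj$positions)[3]

#' @rdname traj_n_frames
#' @export
traj_frame <- function(traj, i) {
  configuration(traj$species, traj$positions[, , i], cell = traj$cell,
                periodic = traj$periodic)
}

#' @rdname traj_n_frames
#' @export
traj_temperature <- function(traj) {
  nfree <- length(traj$species) - length(traj$frozen)
  2 * traj$ekin / (3 * nfree * KB_EV)
}

#' @rdname traj_n_frames
#' @param a,b atom indices.
#' @export
traj_distance <- function(traj, a, b) {
  dx <- traj$positions[a, 1, ] - traj$positions[b, 1, ]
  dy <- traj$positions[a, 2, ] - traj$positions[b, 2, ]
  dz <- traj$positions[a, 3, ] - traj$positions[b, 3, ]
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Stream a trajectory to extended XYZ with a CSV energy sidecar
#'
#' @param traj a `trajectory`.
#' @param path extxyz destination; the sidecar goes to `<path>.csv`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  set <- configuration_set(lapply(seq_len(traj_n_frames(traj)),
                                  function(i) traj_frame(traj, i)))
  write_extxyz(set, path)
  side <- data.frame(time_fs = traj$times, epot_ev = traj$epot,
                     ekin_ev = traj$ekin, temperature_K = traj_temperature(traj))
  if (traj$n_biases > 0) {
    bv <- as.matrix(traj$bias_values)
    colnames(bv) <- paste0("bias", seq_len(ncol(bv)))
    side <- cbind(side, bv)
  }
  utils::write.csv(side, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' Minimize a configuration, optionally under restraints
#'
#' Quasi-Newton (L-BFGS-B) minimization of the potential energy plus any
#' harmonic restraints, with optional frozen atoms; used for relaxed scans
#' and transition-state preparation.
#'
#' @param config starting [configuration()].
#' @param potential a potential object.
#' @param biases list of [harmonic_bias()] restraints.
#' @param frozen_atoms integer indices kept fixed.
#' @param ftol force tolerance (eV/A) on the restrained system.
#' @param maxit iteration cap.
#' @return list with `config` (minimized), `energy` (restraint-free, eV),
#'   `converged`, `fmax`.
#' @export
minimize_config <- function(config, potential, biases = list(),
                            frozen_atoms = integer(0), ftol = 1e-3,
                            maxit = 500L) {
  if (inherits(biases, "harmonic_bias")) biases <- list(biases)
  n <- n_atoms(config)
  free <- setdiff(seq_len(n), as.integer(frozen_atoms))
  x_full <- config$positions
  pack <- function(p) as.numeric(p[free, ])
  unpack <- function(x) { x_full[free, ] <- matrix(x, ncol = 3L); x_full }
  e_and_g <- function(x) {
    pos <- unpack(x)
    cf <- configuration(config$species, pos, config$cell, config$periodic)
    res <- evaluate(potential, cf, forces = TRUE)
    for (b in biases) {
      bb <- bias_eval_r(unclass(b), pos)
      res$energy <- res$energy + bb$energy
      res$forces <- res$forces + bb$forces
    }
    res
  }
  opt <- stats::optim(
    pack(x_full),
    fn = function(x) e_and_g(x)$energy,
    gr = function(x) -as.numeric(e_and_g(x)$forces[free, ]),
    method = "L-BFGS-B",
    control = list(maxit = maxit, factr = 10)
  )
  pos <- unpack(opt$par)
  final <- e_and_g(opt$par)
  fmax <- max(abs(final$forces[free, ]))
  cf <- configuration(config$species, pos, config$cell, config$periodic,
                      provenance = config$provenance)
  plain <- evaluate(potential, cf, forces = FALSE)$energy
  list(config = cf, energy = plain, converged = fmax <= ftol, fmax = fmax)
}
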