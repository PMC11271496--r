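#' Potential contract
#'
#' Anything that maps a [configuration()] to an energy (eV) and per-atom
#' forces (eV/Angstrom) through [evaluate()]. Built-in backends: the
#' analytic [toy_water_potential()] and [two_bond_potential()] (which stand
#' in for ab initio reference calculations at desk scale), simple harmonic
#' test potentials, and the trainable [train_krr()] model. External
#' quantum-chemistry backends are represented by the same contract via
#' [r_function_potential()]: supply any R function returning energy and
#' forces (this is the adapter point for wrapping an external code; no
#' process management is provided here).
#'
#' @param potential a potential object.
#' @param config a [configuration()].
#' @param forces logical; compute forces too?
#' @param ... passed to methods.
#' @return `evaluate()` returns `list(energy = <eV>, forces = <n x 3>)`.
#' @export
evaluate <- function(potential, config, forces = TRUE, ...) {
  UseMethod("evaluate")
}

#' @export
print.mlal_potential <- function(x, ...) {
  cat("<", class(x)[1], "> label '", x$label, "', r_cut ", x$r_cut, " A\n",
      sep = "")
  invisible(x)
}

eval_potspec <- function(potspec, config, species_tab, forces) {
  codes <- match(config$species, species_tab) - 1L
  if (anyNA(codes)) {
    stop("unsupported species for this potential: ",
         paste(unique(config$species[is.na(codes)]), collapse = ", "))
  }
  res <- pot_eval_cpp(potspec, config$positions, as.integer(codes),
                      if (is.null(config$cell)) NULL else config$cell,
                      config$periodic, forces)
  if (!forces) res$forces <- NULL
  res
}

#' Analytic flexible water potential
#'
#' Harmonic O-H bonds and H-O-H angles, O-O Lennard-Jones, and fixed point
#' charges with a smoothly truncated (shifted-force, C1) Coulomb
#' interaction between different molecules. Parameters default to an
#' SPC-like flexible model whose O-O radial distribution peaks near 2.8 A.
#' Serves as the desk-scale ground-truth backend replacing ab initio
#' reference calculations.
#'
#' @param k_bond O-H bond force constant (eV/A^2).
#' @param r0 O-H equilibrium length (A).
#' @param k_angle H-O-H angle force constant (eV/rad^2).
#' @param theta0 equilibrium angle (degrees).
#' @param lj_eps,lj_sigma O-O Lennard-Jones parameters (eV, A).
#' @param q_O,q_H point charges (e).
#' @param coul_rcut Coulomb truncation radius (A); must be below half the
#'   box length for periodic systems.
#' @return a potential object (classes `toy_water_potential`,
#'   `mlal_potential`).
#' @export
toy_water_potential <- function(k_bond = 30, r0 = 0.96, k_angle = 3,
                                theta0 = 104.5, lj_eps = 0.0067,
                                lj_sigma = 3.166, q_O = -0.82, q_H = 0.41,
                                coul_rcut = 9.0) {
  structure(
    list(label = "toy_water", r_cut = coul_rcut,
         params = list(k_bond = k_bond, r0 = r0, k_angle = k_angle,
                       theta0 = theta0 * pi / 180, lj_eps = lj_eps,
                       lj_sigma = lj_sigma, q_O = q_O, q_H = q_H,
                       coul_rcut = coul_rcut)),
    class = c("toy_water_potential", "mlal_potential")
  )
}

water_topology <- function(config) {
  n <- n_atoms(config)
  if (n %% 3L == 0L &&
      identical(config$species, rep(c("O", "H", "H"), n %/% 3L))) {
    # canonical O,H,H ordering: topology fixed by construction, independent
    # of geometry (bonds must not re-wire mid-trajectory)
    mol <- rep(seq_len(n %/% 3L), each = 3L)
    return(list(mol = mol, mols = split(seq_len(n), mol)))
  }
  mol <- molecule_ids(config)
  mols <- split(seq_along(mol), mol)
  for (idx in mols) {
    if (length(idx) != 3L || sum(config$species[idx] == "O") != 1L ||
        sum(config$species[idx] == "H") != 2L) {
      stop("toy water potential expects O,H,H molecules; found a fragment of ",
           paste(config$species[idx], collapse = ""))
    }
  }
  list(mol = mol, mols = mols)
}

as_potspec <- function(potential, config) UseMethod("as_potspec")

#' @export
as_potspec.toy_water_potential <- function(potential, config) {
  p <- potential$params
  topo <- water_topology(config)
  bonds <- NULL; angles <- NULL
  for (idx in topo$mols) {
    o <- idx[config$species[idx] == "O"]
    hs <- idx[config$species[idx] == "H"]
    bonds <- rbind(bonds, c(o, hs[1], p$k_bond, p$r0), c(o, hs[2], p$k_bond, p$r0))
    angles <- rbind(angles, c(hs[1], o, hs[2], p$k_angle, p$theta0))
  }
  os <- which(config$species == "O")
  lj <- if (length(os) > 1L) {
    cmb <- utils::combn(os, 2L)
    cbind(t(cmb), p$lj_eps, p$lj_sigma)
  } else NULL
  charges <- ifelse(config$species == "O", p$q_O, p$q_H)
  list(type = "ff", bonds = bonds, angles = angles, lj = lj,
       charges = charges, mol = as.integer(topo$mol), coul_rcut = p$coul_rcut)
}

#' @export
evaluate.toy_water_potential <- function(potential, config, forces = TRUE, ...) {
  if (config$periodic && !is.null(config$cell)) {
    if (potential$params$coul_rcut > min(sqrt(rowSums(config$cell^2))) / 2) {
      stop("coul_rcut exceeds half the shortest box vector")
    }
  }
  eval_potspec(as_potspec(potential, config), config,
               unique(config$species), forces)
}

#' Two-bond double-well reactive potential
#'
#' A minimal reactive model for a cycloaddition-like process: two designated
#' atom pairs (the forming bonds r1 and r2) each feel a quartic double well
#' `h ((r - c)^2 - w^2)^2 / w^4 + s (r - c)` with a reactant minimum near
#' `c + w`, a product minimum near `c - w` and a barrier of height ~`h`; a
#' coupling term `g (r1 - r2)^2` controls the synchronicity of the two bond
#' formations, and intra-fragment bonds are harmonic. The constrained
#' potential-energy surface over (r1, r2) is available analytically: with
#' both forming bonds held fixed the remaining terms relax to zero, so
#' `U(r1, r2) = V_dw(r1) + V_dw(r2) + g (r1 - r2)^2` (see
#' [two_bond_analytic_pes()]).
#'
#' @param pair1,pair2 atom-index pairs for r1 and r2.
#' @param fragments list of intra-fragment harmonic bonds as rows
#'   `(i, j, k, r0)`; defaults to the [build_two_bond_system()] topology.
#' @param barrier double-well height h (eV).
#' @param centre double-well centre c (A).
#' @param width half-separation w of the wells (A).
#' @param asym linear asymmetry s (eV/A); positive tilts toward the product.
#' @param coupling synchronicity constant g (eV/A^2).
#' @return a potential object (classes `two_bond_potential`, `mlal_potential`).
#' @export
two_bond_potential <- function(pair1 = c(1L, 3L), pair2 = c(2L, 4L),
                               fragments = rbind(c(1, 2, 20, 1.4),
                                                 c(3, 4, 20, 1.4)),
                               barrier = 0.8, centre = 2.35, width = 0.85,
                               asym = 0.05, coupling = 0.1) {
  structure(
    list(label = "two_bond_reactive", r_cut = centre + 3 * width,
         pair1 = as.integer(pair1), pair2 = as.integer(pair2),
         fragments = fragments,
         params = list(h = barrier, c = centre, w = width, s = asym,
                       g = coupling)),
    class = c("two_bond_potential", "mlal_potential")
  )
}

#' @export
as_potspec.two_bond_potential <- function(potential, config) {
  p <- potential$params
  dw <- rbind(c(potential$pair1, p$h, p$c, p$w, p$s),
              c(potential$pair2, p$h, p$c, p$w, p$s))
  list(type = "ff", bonds = potential$fragments, double_wells = dw,
       couplings = matrix(c(potential$pair1, potential$pair2, p$g), nrow = 1L))
}

#' @export
evaluate.two_bond_potential <- function(potential, config, forces = TRUE, ...) {
  eval_potspec(as_potspec(potential, config), config,
               unique(config$species), forces)
}

#' @rdname two_bond_potential
#' @param potential a `two_bond_potential`.
#' @param r1,r2 forming-bond distances (A), possibly vectors.
#' @return `two_bond_analytic_pes()` returns the constrained PES values (eV).
#' @export
two_bond_analytic_pes <- function(potential, r1, r2) {
  p <- potential$params
  vdw <- function(r) {
    t <- r - p$c
    p$h * (t^2 - p$w^2)^2 / p$w^4 + p$s * t
  }
  vdw(r1) + vdw(r2) + p$g * (r1 - r2)^2
}

#' Harmonic pair-distance test potential
#'
#' `E = 0.5 k (r_ij - r0)^2` on one atom pair; used for closed-form checks
#' (oscillator period, biased-sampling variance).
#'
#' @param i,j atom indices.
#' @param k force constant (eV/A^2).
#' @param r0 equilibrium distance (A).
#' @return a potential object.
#' @export
harmonic_pair_potential <- function(i = 1L, j = 2L, k = 1.0, r0 = 1.0) {
  structure(
    list(label = "harmonic_pair", r_cut = Inf,
         spec = list(type = "ff", bonds = matrix(c(i, j, k, r0), nrow = 1L))),
    class = c("ff_potential", "mlal_potential")
  )
}

#' Free (ideal-gas) potential
#'
#' Zero energy and forces everywhere; useful for normalization checks.
#' @return a potential object.
#' @export
free_potential <- function() {
  structure(list(label = "free", r_cut = Inf, spec = list(type = "ff")),
            class = c("ff_potential", "mlal_potential"))
}

#' Double-well pair-distance test potential
#'
#' A single quartic double well on one atom pair; the 1D analogue of the
#' reactive model, used for free-energy benchmarks.
#'
#' @inheritParams two_bond_potential
#' @param i,j atom indices.
#' @export
double_well_pair_potential <- function(i = 1L, j = 2L, barrier = 0.3,
                                       centre = 2.35, width = 0.6, asym = 0) {
  structure(
    list(label = "double_well_pair", r_cut = Inf,
         spec = list(type = "ff",
                     double_wells = matrix(c(i, j, barrier, centre, width, asym),
                                           nrow = 1L)),
         params = list(h = barrier, c = centre, w = width, s = asym)),
    class = c("ff_potential", "mlal_potential")
  )
}

#' @export
as_potspec.ff_potential <- function(potential, config) potential$spec

#' @export
evaluate.ff_potential <- function(potential, config, forces = TRUE, ...) {
  eval_potspec(potential$spec, config, unique(config$species), forces)
}

#' Wrap an R function as a potential backend
#'
#' Adapter for external backends: `fn(config)` must return
#' `list(energy=, forces=)`. MD with such a potential falls back to a pure-R
#' integration loop.
#'
#' @param fn function of a configuration.
#' @param label backend name.
#' @param r_cut nominal interaction cutoff (A).
#' @export
r_function_potential <- function(fn, label = "external", r_cut = 5.0) {
  stopifnot(is.function(fn))
  structure(list(label = label, r_cut = r_cut, fn = fn),
            class = c("r_function_potential", "mlal_potential"))
}

#' @export
evaluate.r_function_potential <- function(potential, config, forces = TRUE, ...) {
  res <- potential$fn(config)
  if (!forces) res$forces <- NULL
  res
}

# ------------------------------------------------------------------- KRR --

#' Train a kernel-ridge-regression potential on global SOAP descriptors
#'
#' The model is a kernel expansion `E(x) = sum_t alpha_t |p(x) . p_t|^zeta
#' + shift` over the unit-normalized global descriptors of the training
#' configurations. With `train_on_forces = FALSE` the weights solve the
#' classic square ridge system `(K + lambda I) alpha = E - mean(E)` with
#' `K_ij = |p_i . p_j|^zeta`. By default the reference forces (when
#' present) enter the fit as well: the model is linear in `alpha` for both
#' energies and force components, so the weights solve a single regularized
#' least-squares problem over energy rows and `force_weight`-scaled force
#' rows - the way kernel and linear interatomic potentials are fitted in
#' practice, and what makes the forces of an energy-only-sized training set
#' usable. Deterministic given (training set, lambda, zeta, weights).
#'
#' @param train_set a [configuration_set()] with reference energies (and
#'   forces, if `train_on_forces`).
#' @param soap a [soap_params()].
#' @param lambda ridge regularization, relative to the mean diagonal of the
#'   normal matrix (the kernel diagonal is 1 for the energy-only path);
#'   lambda = 0 with duplicate descriptors gives a singular system and an
#'   error advising lambda > 0.
#' @param zeta kernel exponent.
#' @param train_on_forces include reference force components in the fit.
#' @param force_weight weight of each force row relative to an energy row
#'   (A; balances eV against eV/A units).
#' @param core_repulsion include a two-body core-repulsion baseline
#'   `A ((r_on/r)^6 - 1)^2` below `r_on` (C1-smooth at `r_on`); the kernel
#'   model then learns the remainder. The wall radius per species pair is
#'   set just inside the closest distance sampled by the training set
#'   (`0.85 x min`), so the model cannot collapse into regions it has never
#'   seen - the standard baseline construction for kernel potentials.
#' @param core_A wall prefactor (eV).
#' @param core optional precomputed baseline (list with `r_on`, `A`),
#'   overriding the data-driven construction.
#' @param force_method `"analytic"` (exact gradient of the kernel energy,
#'   default) or `"fd"` (central finite differences, step `h_fd`).
#' @param h_fd finite-difference step (A).
#' @return an object of classes `soap_krr_mlp`, `mlal_potential`.
#' @export
train_krr <- function(train_set, soap, lambda = 1e-8, zeta = 4L,
                      train_on_forces = TRUE, force_weight = 0.1,
                      core_repulsion = TRUE, core_A = 1.0, core = NULL,
                      force_method = c("analytic", "fd"), h_fd = 1e-3) {
  stopifnot(inherits(train_set, "configuration_set"),
            inherits(soap, "soap_params"))
  force_method <- match.arg(force_method)
  if (!length(train_set)) stop("training set is empty")
  energies <- set_energies(train_set)
  if (anyNA(energies)) {
    stop("missing reference energies for training configurations: ",
         paste(which(is.na(energies)), collapse = ", "))
  }
  if (is.null(core) && core_repulsion) {
    core <- core_from_set(train_set, soap, A = core_A)
  }
  blocks <- lapply(train_set$configs, krr_config_block, soap = soap,
                   jacobian = train_on_forces, core = core)
  krr_fit(blocks, soap, lambda = lambda, zeta = zeta,
          train_on_forces = train_on_forces, force_weight = force_weight,
          core = core, force_method = force_method, h_fd = h_fd)
}

# Data-driven core-repulsion baseline: wall just inside the closest sampled
# distance per species pair (capped at the descriptor cutoff).
core_from_set <- function(train_set, soap, A = 1.0, scale = 0.85) {
  S <- length(soap$species)
  dmin <- matrix(Inf, S, S)
  for (cf in train_set$configs) {
    codes <- species_codes(cf, soap) + 1L
    d <- pair_distances(cf)
    for (s1 in seq_len(S)) for (s2 in seq_len(s1)) {
      di <- d[codes == s1, codes == s2, drop = FALSE]
      di <- di[di > 1e-8]
      if (length(di)) {
        m <- min(di)
        dmin[s1, s2] <- min(dmin[s1, s2], m)
        dmin[s2, s1] <- dmin[s1, s2]
      }
    }
  }
  r_on <- pmin(scale * dmin, soap$r_cut)
  r_on[!is.finite(r_on)] <- 0
  list(r_on = r_on, A = A)
}

core_eval_config <- function(config, soap, core) {
  codes <- species_codes(config, soap)
  core_eval_cpp(config$positions, codes, length(soap$species),
                core$r_on, core$A,
                if (is.null(config$cell)) NULL else config$cell,
                config$periodic)
}

# Per-configuration descriptor block: normalized global vector, its norm,
# optionally the Jacobian of the unnormalised vector, and the labels.
krr_config_block <- function(config, soap, jacobian = TRUE, core = NULL) {
  codes <- species_codes(config, soap)
  res <- soap_global_cpp(config$positions, codes, soap_spec_cpp(soap),
                         if (is.null(config$cell)) NULL else config$cell,
                         config$periodic, jacobian)
  nrm <- sqrt(sum(res$q^2))
  if (nrm < 1e-300) stop("empty descriptor: no atom has neighbours within r_cut")
  energy <- config$energy
  forces <- if (is.null(config$forces)) NULL else config$forces
  if (!is.null(core) && !is.null(energy)) {
    cc <- core_eval_config(config, soap, core)
    energy <- energy - cc$energy
    if (!is.null(forces)) forces <- forces - cc$forces
  }
  list(pbar = res$q / nrm, norm = nrm, jacobian = res$jacobian,
       energy = energy,
       forces = if (is.null(forces)) NULL else as.numeric(t(forces)))
}

krr_fit <- function(blocks, soap, lambda = 1e-8, zeta = 4L,
                    train_on_forces = TRUE, force_weight = 0.1,
                    core = NULL, force_method = "analytic", h_fd = 1e-3) {
  zeta <- as.integer(zeta)
  P <- do.call(rbind, lapply(blocks, `[[`, "pbar"))
  energies <- vapply(blocks, `[[`, numeric(1), "energy")
  K <- abs(P %*% t(P))^zeta
  shift <- mean(energies)
  yE <- energies - shift
  have_forces <- train_on_forces &&
    all(vapply(blocks, function(b) !is.null(b$forces), logical(1)))
  if (!have_forces) {
    alpha <- tryCatch(
      solve(K + diag(lambda, nrow(K)), yE),
      error = function(e) {
        stop("kernel system is singular (duplicate descriptors at lambda = ",
             lambda, "); use lambda > 0. Underlying error: ",
             conditionMessage(e))
      }
    )
  } else {
    rowsA <- list(K)
    rowsY <- list(yE)
    for (b in blocks) {
      s <- as.numeric(P %*% b$pbar)
      coefs <- zeta * abs(s)^(zeta - 1) * sign(s) / b$norm
      G <- (P - outer(s, b$pbar)) * coefs
      # predicted forces are -t(M) %*% alpha with M = G J
      rowsA[[length(rowsA) + 1L]] <- -force_weight * t(G %*% b$jacobian)
      rowsY[[length(rowsY) + 1L]] <- force_weight * b$forces
    }
    A <- do.call(rbind, rowsA)
    y <- unlist(rowsY)
    AtA <- crossprod(A)
    reg <- lambda * mean(diag(AtA))
    alpha <- tryCatch(
      solve(AtA + diag(reg, nrow(AtA)), crossprod(A, y)),
      error = function(e) {
        stop("normal equations are singular (lambda = ", lambda,
             "); use lambda > 0. Underlying error: ", conditionMessage(e))
      }
    )
  }
  structure(
    list(label = "mlp", r_cut = soap$r_cut, soap = soap,
         train_descriptors = P, alpha = as.numeric(alpha), zeta = zeta,
         shift = shift, lambda = lambda, core = core,
         train_on_forces = have_forces, force_weight = force_weight,
         force_method = force_method, h_fd = h_fd, n_train = nrow(P)),
    class = c("soap_krr_mlp", "mlal_potential")
  )
}

#' @export
as_potspec.soap_krr_mlp <- function(potential, config = NULL) {
  list(type = "krr", soap = soap_spec_cpp(potential$soap),
       train_descriptors = potential$train_descriptors,
       alpha = potential$alpha, zeta = as.numeric(potential$zeta),
       shift = potential$shift,
       core_r_on = if (is.null(potential$core)) NULL else potential$core$r_on,
       core_A = if (is.null(potential$core)) NULL else potential$core$A)
}

#' Predict energy and forces with a trained KRR potential
#'
#' Energy is the kernel row against the training descriptors dotted with
#' the weights plus the mean shift. Forces are the exact negative gradient
#' of that energy by default, or central finite differences (6N extra
#' descriptor evaluations) when the model was built with
#' `force_method = "fd"`.
#'
#' @param object a `soap_krr_mlp` from [train_krr()].
#' @param config a [configuration()].
#' @param forces logical.
#' @param ... unused.
#' @return `list(energy, forces)`.
#' @export
predict.soap_krr_mlp <- function(object, config, forces = TRUE, ...) {
  evaluate(object, config, forces = forces)
}

#' @export
evaluate.soap_krr_mlp <- function(potential, config, forces = TRUE, ...) {
  if (is.null(potential$alpha)) stop("model is not trained")
  codes <- species_codes(config, potential$soap)
  spec <- as_potspec(potential)
  if (!forces || potential$force_method == "analytic") {
    res <- pot_eval_cpp(spec, config$positions, codes,
                        if (is.null(config$cell)) NULL else config$cell,
                        config$periodic, forces)
    if (!forces) res["forces"] <- list(NULL)
    return(res)
  }
  # finite-difference forces on top of the analytic energy
  e0 <- pot_eval_cpp(spec, config$positions, codes,
                     if (is.null(config$cell)) NULL else config$cell,
                     config$periodic, FALSE)$energy
  h <- potential$h_fd
  n <- n_atoms(config)
  F <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    for (d in 1:3) {
      pp <- config$positions; pp[i, d] <- pp[i, d] + h
      ep <- pot_eval_cpp(spec, pp, codes,
                         if (is.null(config$cell)) NULL else config$cell,
                         config$periodic, FALSE)$energy
      pm <- config$positions; pm[i, d] <- pm[i, d] - h
      em <- pot_eval_cpp(spec, pm, codes,
                         if (is.null(config$cell)) NULL else config$cell,
                         config$periodic, FALSE)$energy
      F[i, d] <- -(ep - em) / (2 * h)
    }
  }
  list(energy = e0, forces = F)
}

#' Mean absolute deviation of a model against a reference
#'
#' `MAD_energy` is the mean absolute energy deviation per configuration,
#' `MAD_forces` the mean absolute deviation over all force components
#' (atoms x 3 x configurations); both reported in kcal/mol (/A).
#'
#' @param model,reference potential objects.
#' @param eval_set a non-empty [configuration_set()].
#' @return `list(mad_energy, mad_forces)` in kcal/mol and kcal/mol/A.
#' @export
mad_metrics <- function(model, reference, eval_set) {
  if (!length(eval_set)) stop("evaluation set is empty")
  de <- numeric(0); df <- numeric(0)
  for (cf in eval_set$configs) {
    a <- evaluate(model, cf, forces = TRUE)
    b <- evaluate(reference, cf, forces = TRUE)
    de <- c(de, abs(a$energy - b$energy))
    df <- c(df, abs(a$forces - b$forces))
  }
  list(mad_energy = mean(de) * EV_TO_KCAL_MOL,
       mad_forces = mean(df) * EV_TO_KCAL_MOL)
}

# --------------------------------------------------------- serialization --

#' Save / load a trained KRR potential
#'
#' Plain-text JSON serialization: a header carrying the descriptor
#' hyperparameters (and their hash) plus the weight and descriptor blocks at
#' full precision. `load_mlp()` refuses to load when `expect_params` is
#' given and its hash does not match the stored one.
#'
#' @param model a `soap_krr_mlp`.
#' @param path file path.
#' @param expect_params optional [soap_params()] the caller requires.
#' @return `load_mlp()` returns the model; `save_mlp()` the path, invisibly.
#' @export
save_mlp <- function(model, path) {
  stopifnot(inherits(model, "soap_krr_mlp"))
  obj <- list(
    header = list(format = "mlal-krr-1",
                  params_hash = soap_params_hash(model$soap),
                  soap = unclass(model$soap), zeta = model$zeta,
                  lambda = model$lambda, shift = model$shift,
                  force_method = model$force_method, h_fd = model$h_fd,
                  n_train = model$n_train),
    core = model$core,
    alpha = model$alpha,
    train_descriptors = model$train_descriptors
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path, expect_params = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hd <- obj$header
  soap <- soap_params(hd$soap$species, hd$soap$r_cut, hd$soap$n_max,
                      hd$soap$l_max, hd$soap$sigma_atom, hd$soap$average)
  if (!is.null(expect_params)) {
    if (!identical(soap_params_hash(expect_params), hd$params_hash)) {
      stop("descriptor-parameter hash mismatch: model was trained with ",
           hd$params_hash, ", caller expects ",
           soap_params_hash(expect_params))
    }
  }
  core <- NULL
  if (!is.null(obj$core)) {
    core <- list(r_on = as.matrix(obj$core$r_on), A = obj$core$A)
  }
  structure(
    list(label = "mlp", r_cut = soap$r_cut, soap = soap,
         train_descriptors = as.matrix(obj$train_descriptors),
         alpha = as.numeric(obj$alpha), zeta = as.integer(hd$zeta),
         shift = hd$shift, lambda = hd$lambda, core = core,
         force_method = hd$force_method, h_fd = hd$h_fd,
         n_train = hd$n_train),
    class = c("soap_krr_mlp", "mlal_potential")
  )
}
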