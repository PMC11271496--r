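#' Episode schedule of the active-learning loop
#'
#' The duration of the `n`-th MD episode within one selection streak is
#' `n^3 + 2` fs, with `n` starting from 0 and resetting to 0 after every
#' accepted structure: episodes of 2, 3, 10, 29, 66, ... fs probe the model
#' close to the training data first and push further out only while it
#' keeps passing.
#'
#' @param n episode index within the current streak (integer >= 0).
#' @return episode duration in fs.
#' @examples
#' md_schedule(0)  # 2 fs
#' md_schedule(2)  # 10 fs
#' @export
md_schedule <- function(n) {
  n <- as.integer(n)
  if (any(is.na(n)) || any(n < 0L)) stop("episode index n must be >= 0")
  n^3 + 2
}

#' Active-learning configuration
#'
#' @param selector `"energy"`, `"similarity"` or `"distance"`.
#' @param selector_config matching selector config object; defaults to the
#'   selector's default construction ([energy_selector_config()] needs an
#'   explicit `E_T`, so it has no default here).
#' @param soap a [soap_params()] used for descriptors and the KRR model.
#' @param lambda,zeta,train_on_forces,force_weight KRR hyperparameters (see
#'   [train_krr()]).
#' @param temperature,dt,friction MD-episode settings (K, fs, 1/fs).
#' @param max_time maximum episode duration before the loop is declared
#'   converged (fs; default 5000 = 5 ps).
#' @param max_al_iterations hard cap on MD episodes.
#' @param max_label_energy_per_atom labelling guard (eV/atom): a selected
#'   candidate whose reference energy lies more than this above the
#'   training-set minimum (per atom) fails labelling and is dropped with
#'   `n` incremented - the desk-scale analogue of a non-physical structure
#'   whose reference calculation does not converge. `NULL` disables.
#' @param rng_seed master seed; episode seeds derive from it.
#' @param start_index which member of the initial set seeds the episodes.
#' @param loop_force_atoms number of atoms per configuration whose force
#'   components enter the per-acceptance loop refits (the final fit uses
#'   all of them).
#' @param start_mode `"fixed"`: every episode starts from the designated
#'   initial-set structure (the default); `"latest"`: episodes restart from
#'   the most recently accepted structure, maximizing exploration
#'   continuity at the price of a harder-to-saturate selector.
#' @return an object of class `al_config`.
#' @export
al_config <- function(selector = c("similarity", "energy", "distance"),
                      selector_config = NULL, soap, lambda = 1e-8, zeta = 4L,
                      train_on_forces = TRUE, force_weight = 0.1,
                      temperature = 300, dt = 0.5, friction = 0.02,
                      max_time = 5000, max_al_iterations = 500L,
                      max_label_energy_per_atom = 0.12,
                      rng_seed = 1L, start_index = 1L,
                      start_mode = c("fixed", "latest"),
                      loop_force_atoms = 8L) {
  selector <- match.arg(selector)
  start_mode <- match.arg(start_mode)
  if (max_time <= 0) stop("max_time must be positive")
  if (is.null(selector_config)) {
    selector_config <- switch(selector,
      similarity = similarity_selector_config(),
      distance = distance_selector_config(),
      energy = stop("energy selector requires an explicit ",
                    "energy_selector_config(E_T)")
    )
  }
  expected <- paste0(selector, "_selector_config")
  if (!inherits(selector_config, expected)) {
    stop("selector_config must be a ", expected)
  }
  stopifnot(inherits(soap, "soap_params"))
  structure(
    list(selector = selector, selector_config = selector_config, soap = soap,
         lambda = lambda, zeta = as.integer(zeta),
         train_on_forces = isTRUE(train_on_forces),
         force_weight = force_weight, temperature = temperature,
         dt = dt, friction = friction, max_time = max_time,
         max_al_iterations = as.integer(max_al_iterations),
         max_label_energy_per_atom = max_label_energy_per_atom,
         rng_seed = as.integer(rng_seed), start_index = as.integer(start_index),
         start_mode = start_mode,
         loop_force_atoms = as.integer(loop_force_atoms)),
    class = "al_config"
  )
}

# Incremental energy+force KRR fitter for the AL loop: caches the kernel
# matrix and the descriptor-Jacobian projections so the per-acceptance
# refit costs O(T^3) instead of rebuilding the design from scratch. Force
# rows are restricted to a fixed per-configuration atom subset
# (n_force_atoms) during the loop; the final returned model is refitted on
# everything.
krr_incremental_fitter <- function(soap, lambda, zeta, force_weight,
                                   n_force_atoms = 8L, core = NULL) {
  env <- new.env(parent = emptyenv())
  env$P <- NULL; env$S <- NULL
  env$PJ <- list(); env$Jsub <- list(); env$pbarJ <- list()
  env$E <- numeric(0); env$Fsub <- list(); env$norms <- numeric(0)
  add <- function(config) {
    blk <- krr_config_block(config, soap, jacobian = TRUE, core = core)
    N <- nrow(config$positions)
    atoms <- if (N <= n_force_atoms) seq_len(N) else
      unique(round(seq(1, N, length.out = n_force_atoms)))
    cols <- as.vector(vapply(atoms, function(a) (3L * (a - 1L) + 1L):(3L * a),
                             integer(3)))
    Js <- blk$jacobian[, cols, drop = FALSE]
    p <- blk$pbar
    T0 <- if (is.null(env$P)) 0L else nrow(env$P)
    if (T0 > 0L) {
      s_new <- as.numeric(env$P %*% p)
      env$S <- rbind(cbind(env$S, s_new), c(s_new, 1))
      for (cc in seq_len(T0)) {
        env$PJ[[cc]] <- rbind(env$PJ[[cc]], as.numeric(p %*% env$Jsub[[cc]]))
      }
    } else {
      env$S <- matrix(1, 1L, 1L)
    }
    env$P <- rbind(env$P, p)
    env$Jsub[[T0 + 1L]] <- Js
    env$PJ[[T0 + 1L]] <- env$P %*% Js
    env$pbarJ[[T0 + 1L]] <- as.numeric(p %*% Js)
    env$norms <- c(env$norms, blk$norm)
    env$E <- c(env$E, blk$energy)
    env$Fsub[[T0 + 1L]] <- blk$forces[cols]
    invisible(NULL)
  }
  fit <- function() {
    T0 <- nrow(env$P)
    K <- abs(env$S)^zeta
    shift <- mean(env$E)
    rowsA <- vector("list", T0 + 1L)
    rowsY <- vector("list", T0 + 1L)
    rowsA[[1L]] <- K; rowsY[[1L]] <- env$E - shift
    for (cc in seq_len(T0)) {
      s <- env$S[, cc]
      coefs <- zeta * abs(s)^(zeta - 1) * sign(s) / env$norms[cc]
      M <- (env$PJ[[cc]] - outer(s, env$pbarJ[[cc]])) * coefs
      rowsA[[cc + 1L]] <- -force_weight * t(M)
      rowsY[[cc + 1L]] <- force_weight * env$Fsub[[cc]]
    }
    A <- do.call(rbind, rowsA)
    y <- unlist(rowsY)
    AtA <- crossprod(A)
    reg <- lambda * mean(diag(AtA))
    alpha <- solve(AtA + diag(reg, T0), crossprod(A, y))
    structure(
      list(label = "mlp", r_cut = soap$r_cut, soap = soap,
           train_descriptors = env$P, alpha = as.numeric(alpha),
           zeta = as.integer(zeta), shift = shift, lambda = lambda,
           core = core, train_on_forces = TRUE, force_weight = force_weight,
           force_method = "analytic", h_fd = 1e-3, n_train = T0),
      class = c("soap_krr_mlp", "mlal_potential"))
  }
  list(add = add, fit = fit, env = env)
}

label_with_reference <- function(config, reference, tag = NULL) {
  res <- evaluate(reference, config, forces = TRUE)
  prov <- config$provenance
  if (!is.null(tag)) prov <- c(prov, tag)
  configuration(config$species, config$positions, config$cell,
                config$periodic, energy = res$energy, forces = res$forces,
                label = "reference", provenance = prov)
}

#' Run the active-learning loop
#'
#' Trains an initial KRR model on the (reference-labelled) initial set,
#' then repeats: run an MD episode of [md_schedule()]`(n)` fs with the
#' current model from the episode start structure (a designated member of
#' the initial training set, or the most recently accepted structure under
#' `start_mode = "latest"`), evaluate the episode's last frame with
#' the selector, and
#' * on **add**: label the frame with the reference backend, append it,
#'   retrain, reset `n <- 0`;
#' * on **skip**: increment `n`;
#' * on **discard** (energy selector only): drop the frame and increment
#'   `n`.
#'
#' The loop terminates (converged) when the next episode duration would
#' exceed `max_time` without any selection, or (not converged) at
#' `max_al_iterations`. An unstable episode still yields a candidate frame
#' - frames where the model blows up are exactly the ones worth selecting -
#' unless coordinates went non-finite, in which case the episode is retried
#' with a fresh seed and `n` unchanged (logged).
#'
#' @param initial_set a [configuration_set()]; members lacking reference
#'   labels are labelled by `reference` on entry.
#' @param reference the ground-truth potential backend.
#' @param cfg an [al_config()].
#' @return list with `model` (trained [train_krr()] potential),
#'   `training_set` (provenance-rich [configuration_set()]), `log` (one row
#'   per episode: iteration, n, duration, selector, score, threshold,
#'   verdict, unstable, reference_calls), `converged`.
#' @export
al_train <- function(initial_set, reference, cfg) {
  stopifnot(inherits(initial_set, "configuration_set"),
            inherits(cfg, "al_config"))
  if (!length(initial_set)) stop("initial set is empty")
  configs <- lapply(initial_set$configs, function(cf) {
    if (is.null(cf$energy) || is.null(cf$forces)) {
      label_with_reference(cf, reference)
    } else cf
  })
  training <- configuration_set(configs, name = "al_training",
                                log = "initialized from initial set")
  if (cfg$selector == "distance" &&
      length(training) < cfg$selector_config$min_initial_size) {
    stop("distance selector requires an initial set of at least ",
         "min_initial_size = ", cfg$selector_config$min_initial_size,
         " configurations (got ", length(training), ")")
  }
  # Loop refits train on energies plus a fixed per-configuration subset of
  # force components through an incremental cache; the returned model is
  # refitted once at the end on all labels.
  core <- core_from_set(training, cfg$soap)
  if (cfg$train_on_forces) {
    fitter <- krr_incremental_fitter(cfg$soap, cfg$lambda, cfg$zeta,
                                     cfg$force_weight, cfg$loop_force_atoms,
                                     core = core)
    for (cf in training$configs) fitter$add(cf)
    refit <- fitter$fit
    register <- fitter$add
  } else {
    blocks <- lapply(training$configs, krr_config_block, soap = cfg$soap,
                     jacobian = FALSE, core = core)
    refit <- function() {
      krr_fit(blocks, cfg$soap, lambda = cfg$lambda, zeta = cfg$zeta,
              train_on_forces = FALSE, core = core)
    }
    register <- function(cf) {
      blocks[[length(blocks) + 1L]] <<- krr_config_block(cf, cfg$soap,
                                                         jacobian = FALSE,
                                                         core = core)
    }
  }
  model <- refit()
  desc <- model$train_descriptors
  start <- training[[min(cfg$start_index, length(training))]]
  n <- 0L
  reference_calls <- 0L
  converged <- FALSE
  log <- list()
  iter <- 0L
  retries <- 0L
  while (iter < cfg$max_al_iterations) {
    dur <- md_schedule(n)
    if (dur > cfg$max_time) { converged <- TRUE; break }
    iter <- iter + 1L
    seed <- (cfg$rng_seed * 1000L + iter * 7L + retries * 131L) %% .Machine$integer.max
    params <- md_params(dt = cfg$dt, temperature = cfg$temperature,
                        ensemble = "nvt", friction = cfg$friction,
                        duration = dur, rng_seed = seed)
    traj <- run_md(start, model, params, stride = max(1L, as.integer(dur / cfg$dt)))
    cand <- traj$final
    if (any(!is.finite(cand$positions))) {
      # numerical blow-up beyond recovery: retry episode with a fresh seed
      retries <- retries + 1L
      log[[length(log) + 1L]] <- data.frame(
        iteration = iter, n = n, duration = dur, selector = cfg$selector,
        score = NA_real_, threshold = NA_real_, verdict = "retry",
        unstable = TRUE, reference_calls = reference_calls)
      next
    }
    if (cfg$selector == "energy") {
      e_ref <- evaluate(reference, cand, forces = FALSE)$energy
      reference_calls <- reference_calls + 1L
      e_mlp <- evaluate(model, cand, forces = FALSE)$energy
      dec <- energy_select(e_ref, e_mlp, cfg$selector_config)
    } else {
      p_new <- compute_soap(cand, cfg$soap)
      dec <- if (cfg$selector == "similarity") {
        similarity_select(p_new, desc, cfg$selector_config)
      } else {
        distance_select(p_new, desc, cfg$selector_config)
      }
    }
    log[[length(log) + 1L]] <- data.frame(
      iteration = iter, n = n, duration = dur, selector = cfg$selector,
      score = dec$score, threshold = dec$threshold_used,
      verdict = dec$verdict, unstable = traj$unstable,
      reference_calls = reference_calls)
    if (dec$verdict == "add") {
      labelled <- label_with_reference(
        cand, reference,
        tag = list(al_iteration = iter, n = n, selector = cfg$selector,
                   verdict = "add"))
      reference_calls <- reference_calls + 1L
      cap <- cfg$max_label_energy_per_atom
      if (!is.null(cap) &&
          labelled$energy - min(set_energies(training)) >
            cap * n_atoms(labelled)) {
        # non-physical candidate: labelling fails, treat as non-selection
        log[[length(log)]]$verdict <- "label_failed"
        n <- n + 1L
        next
      }
      training <- append_config(training, labelled,
                                note = sprintf("iteration %d: added (score %.6g)",
                                               iter, dec$score))
      register(labelled)
      model <- refit()
      desc <- model$train_descriptors
      if (cfg$start_mode == "latest") start <- labelled
      n <- 0L
    } else {
      n <- n + 1L
    }
  }
  if (cfg$train_on_forces) {
    model <- train_krr(training, cfg$soap, lambda = cfg$lambda,
                       zeta = cfg$zeta, train_on_forces = TRUE,
                       force_weight = cfg$force_weight, core = core)
  }
  list(model = model, training_set = training,
       log = do.call(rbind, log), converged = converged,
       reference_calls = reference_calls)
}

#' Write a selector decision log as JSON lines
#'
#' @param log the `log` data.frame from [al_train()].
#' @param path destination file.
#' @export
write_decision_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}

#' Build the independent training subsets of a solvated reactive system
#'
#' The training set for a reaction in explicit solvent is assembled from
#' four independently learned subsets: the bare substrate (intramolecular
#' interactions and intrinsic reactivity), the substrate with a few solvent
#' molecules (specific solute-solvent contacts), the substrate inside a
#' solvent cluster (bulk-like solvation), and pure solvent (solvent-solvent
#' interactions). All subsets start their active learning from the
#' transition-state structure except the pure-solvent subset, which starts
#' from a random solvent configuration.
#'
#' @param system_spec list with elements `subsets` (a named list; each
#'   entry has `start` (a [configuration()]), optional `n_initial`
#'   (default 10), `max_disp` (default 0.1 A)), and optionally shared
#'   items documented in the subset entries.
#' @param cfg the [al_config()] template applied to every subset (seeds are
#'   offset per subset for independence).
#' @return list of jobs, each `list(name, initial_set, cfg)`.
#' @export
build_subsets <- function(system_spec, cfg) {
  if (is.null(system_spec$subsets) || !length(system_spec$subsets)) {
    stop("system_spec$subsets must name at least one subset")
  }
  jobs <- list()
  for (i in seq_along(system_spec$subsets)) {
    ss <- system_spec$subsets[[i]]
    name <- names(system_spec$subsets)[i]
    if (is.null(name) || !nzchar(name)) name <- paste0("subset", i)
    if (is.null(ss$start)) {
      stop("subset '", name, "' is missing its AL start structure")
    }
    n_initial <- ss$n_initial %||% 10L
    max_disp <- ss$max_disp %||% 0.1
    init <- random_displace(ss$start, max_disp = max_disp, count = n_initial,
                            rng_seed = cfg$rng_seed + i)
    init$configs <- lapply(init$configs, function(cf) {
      cf$provenance$subset <- name
      cf
    })
    sub_cfg <- cfg
    sub_cfg$rng_seed <- cfg$rng_seed + 1000L * i
    jobs[[name]] <- list(name = name, initial_set = init, cfg = sub_cfg)
  }
  jobs
}

#' Run all subset jobs and assemble the final model
#'
#' Runs [al_train()] per subset, concatenates the per-subset training sets
#' (provenance tags intact), removes configurations that are duplicates in
#' descriptor space (kernel similarity within `1e-12` of 1), and performs a
#' final full retrain.
#'
#' @param jobs output of [build_subsets()].
#' @param reference ground-truth potential.
#' @return list with `model`, `training_set`, `runs` (per-subset
#'   [al_train()] results), `n_duplicates_removed`.
#' @export
al_train_subsets <- function(jobs, reference) {
  runs <- lapply(jobs, function(j) al_train(j$initial_set, reference, j$cfg))
  all_cfgs <- do.call(c, lapply(runs, function(r) r$training_set$configs))
  combined <- configuration_set(all_cfgs, name = "combined_subsets")
  cfg0 <- jobs[[1]]$cfg
  desc <- do.call(rbind, lapply(combined$configs, function(cf) {
    as.numeric(compute_soap(cf, cfg0$soap))
  }))
  keep <- !duplicated(round(desc, 12))
  dedup <- configuration_set(combined$configs[keep], name = "final_training")
  model <- train_krr(dedup, cfg0$soap, lambda = cfg0$lambda,
                     zeta = cfg0$zeta,
                     train_on_forces = cfg0$train_on_forces,
                     force_weight = cfg0$force_weight)
  list(model = model, training_set = dedup, runs = runs,
       n_duplicates_removed = sum(!keep))
}
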