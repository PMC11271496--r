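#' Atomic configuration
#'
#' The basic data record of the package: one atomic structure with element
#' symbols, Cartesian coordinates and, optionally, a lattice, a labelled
#' energy and per-atom forces. Energy and force labels always carry the name
#' of the backend that produced them; mixing labels from two backends on one
#' record is an error, so a record is either fully reference-labelled or
#' fully model-labelled.
#'
#' @param species character vector of element symbols.
#' @param positions numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param cell optional 3 x 3 matrix of lattice row vectors (Angstrom).
#' @param periodic logical; if `TRUE`, `cell` must be non-singular.
#' @param energy optional scalar potential energy (eV).
#' @param forces optional n x 3 matrix of forces (eV/Angstrom).
#' @param label backend name for `energy`/`forces` (e.g. `"reference"`,
#'   `"mlp"`). Required when either is given.
#' @param provenance named list of free-form tags (subset, AL iteration,
#'   selector, ...).
#' @return an object of class `configuration`.
#' @examples
#' conf <- configuration(
#'   species = c("O", "H", "H"),
#'   positions = rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
#' )
#' n_atoms(conf)
#' @export
configuration <- function(species, positions, cell = NULL, periodic = FALSE,
                          energy = NULL, forces = NULL, label = NULL,
                          provenance = list()) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L) stop("positions must be an n x 3 matrix")
  n <- nrow(positions)
  species <- as.character(species)
  if (length(species) != n) {
    stop("species (", length(species), ") and positions (", n,
         ") have different atom counts")
  }
  if (!all(is.finite(positions))) stop("non-finite coordinates")
  if (!is.null(forces)) {
    forces <- as.matrix(forces)
    storage.mode(forces) <- "double"
    if (!identical(dim(forces), dim(positions))) {
      stop("forces must match positions in shape (", n, " x 3)")
    }
    if (!all(is.finite(forces))) stop("non-finite forces")
  }
  if (!is.null(energy)) {
    energy <- as.numeric(energy)
    if (length(energy) != 1L || !is.finite(energy)) stop("energy must be a finite scalar")
  }
  if ((!is.null(energy) || !is.null(forces)) && is.null(label)) {
    stop("energy/forces require a backend label")
  }
  if (isTRUE(periodic)) {
    if (is.null(cell)) stop("periodic configuration requires a cell")
    cell <- as.matrix(cell)
    if (!identical(dim(cell), c(3L, 3L))) stop("cell must be 3 x 3")
    if (abs(det(cell)) < 1e-10) stop("periodic cell is singular")
  } else if (!is.null(cell)) {
    cell <- as.matrix(cell)
    if (!identical(dim(cell), c(3L, 3L))) stop("cell must be 3 x 3")
  }
  structure(
    list(species = species, positions = positions, cell = cell,
         periodic = isTRUE(periodic), energy = energy, forces = forces,
         label = label, provenance = provenance),
    class = "configuration"
  )
}

#' @rdname configuration
#' @param x a `configuration`.
#' @export
n_atoms <- function(x) {
  stopifnot(inherits(x, "configuration"))
  nrow(x$positions)
}

#' Attach energy/force labels from one backend
#'
#' @param config a [configuration()].
#' @param energy scalar energy (eV).
#' @param forces optional n x 3 force matrix (eV/Angstrom).
#' @param label backend name.
#' @return the relabelled configuration.
#' @export
set_labels <- function(config, energy, forces = NULL, label) {
  configuration(config$species, config$positions, config$cell, config$periodic,
                energy = energy, forces = forces, label = label,
                provenance = config$provenance)
}

#' @export
print.configuration <- function(x, ...) {
  cat("<configuration> ", n_atoms(x), " atoms (",
      paste(names(table(x$species)), table(x$species), sep = ":", collapse = " "),
      ")", if (x$periodic) " periodic" else "", "\n", sep = "")
  if (!is.null(x$energy)) {
    cat("  energy: ", format(x$energy), " eV [", x$label, "]\n", sep = "")
  }
  if (length(x$provenance)) {
    cat("  provenance:", paste(names(x$provenance), unlist(lapply(x$provenance, format)),
                               sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Ordered collection of configurations
#'
#' An append-only ordered list of [configuration()] records with a name and a
#' creation log; the container used for training sets during active
#' learning.
#'
#' @param configs list of `configuration` objects.
#' @param name character name of the set.
#' @param log character vector of creation-log lines.
#' @return an object of class `configuration_set`.
#' @export
configuration_set <- function(configs = list(), name = "set", log = character()) {
  if (inherits(configs, "configuration")) configs <- list(configs)
  if (!all(vapply(configs, inherits, logical(1), "configuration"))) {
    stop("all members must be configuration objects")
  }
  structure(list(configs = configs, name = name, log = log),
            class = "configuration_set")
}

#' @export
length.configuration_set <- function(x) length(x$configs)

#' @export
`[[.configuration_set` <- function(x, i) x$configs[[i]]

#' @export
`[.configuration_set` <- function(x, i) {
  configuration_set(x$configs[i], name = x$name, log = x$log)
}

#' Append configurations to a set
#'
#' @param set a [configuration_set()].
#' @param config a `configuration` or list of them.
#' @param note optional log line.
#' @return the grown set (sets are append-only: members are never removed).
#' @export
append_config <- function(set, config, note = NULL) {
  stopifnot(inherits(set, "configuration_set"))
  if (inherits(config, "configuration")) config <- list(config)
  set$configs <- c(set$configs, config)
  if (!is.null(note)) set$log <- c(set$log, note)
  set
}

#' Deterministic train/held-out split
#'
#' @param set a [configuration_set()].
#' @param fraction fraction assigned to the training part.
#' @param seed integer RNG seed; the same seed always yields the same split.
#' @return list with `train` and `heldout` configuration sets.
#' @export
split_set <- function(set, fraction = 0.8, seed = 1L) {
  n <- length(set)
  stopifnot(n >= 2L, fraction > 0, fraction < 1)
  idx <- withr_seed(seed, sample.int(n, size = max(1L, floor(fraction * n))))
  list(train = set[sort(idx)], heldout = set[setdiff(seq_len(n), idx)])
}

# Evaluate expr under a local RNG seed without disturbing the global stream.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.configuration_set <- function(x, ...) {
  cat("<configuration_set> '", x$name, "': ", length(x), " configurations\n",
      sep = "")
  invisible(x)
}

#' Collect energies of a set
#'
#' @param set a [configuration_set()].
#' @return numeric vector (NA where unlabelled).
#' @export
set_energies <- function(set) {
  vapply(set$configs, function(cf) if (is.null(cf$energy)) NA_real_ else cf$energy,
         numeric(1))
}
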