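#' SOAP descriptor parameters
#'
#' Hyperparameters of the SOAP-style power-spectrum descriptor. Per atom,
#' the neighbour density within `r_cut` is expanded on `n_max` Gaussian
#' radial channels (width `sigma_atom`, centres equally spaced on
#' `[0, r_cut)`) per species, and the rotationally invariant power spectrum
#' is accumulated up to angular momentum `l_max` via Legendre polynomials of
#' neighbour-pair angles. The global descriptor of a configuration is the
#' per-atom average, unit-normalized.
#'
#' @param species character vector of element symbols the descriptor knows;
#'   must be a superset of the species of any configuration passed.
#' @param r_cut neighbour cutoff (Angstrom).
#' @param n_max number of radial channels (>= 1).
#' @param l_max maximum angular momentum (>= 1).
#' @param sigma_atom Gaussian width of the radial channels (Angstrom).
#' @param average logical; global averaging over atoms (the only supported
#'   mode for selector use).
#' @return an object of class `soap_params`.
#' @export
soap_params <- function(species, r_cut = 5.0, n_max = 6L, l_max = 4L,
                        sigma_atom = 0.5, average = TRUE) {
  species <- as.character(species)
  if (!length(species)) stop("species must be non-empty")
  if (anyDuplicated(species)) stop("duplicate species")
  if (r_cut <= 0) stop("r_cut must be positive")
  n_max <- as.integer(n_max); l_max <- as.integer(l_max)
  if (n_max < 1L || l_max < 1L) stop("n_max and l_max must be >= 1")
  if (sigma_atom <= 0) stop("sigma_atom must be positive")
  structure(
    list(species = species, r_cut = r_cut, n_max = n_max, l_max = l_max,
         sigma_atom = sigma_atom, average = isTRUE(average)),
    class = "soap_params"
  )
}

soap_spec_cpp <- function(params) {
  list(r_cut = params$r_cut, n_max = params$n_max, l_max = params$l_max,
       sigma_atom = params$sigma_atom, n_species = length(params$species))
}

species_codes <- function(config, params) {
  codes <- match(config$species, params$species) - 1L
  if (anyNA(codes)) {
    bad <- unique(config$species[is.na(codes)])
    stop("element(s) not in descriptor species list: ",
         paste(bad, collapse = ", "))
  }
  as.integer(codes)
}

#' Compute the global SOAP descriptor of a configuration
#'
#' Deterministic, and invariant to rigid translations and rotations of the
#' configuration and (in averaged mode) to reordering of atoms within a
#' species.
#'
#' @param config a [configuration()].
#' @param params a [soap_params()] whose species cover the configuration.
#' @return an object of class `descriptor_vector`: unit-normalized numeric
#'   vector with attributes `params_hash` and `n_atoms`.
#' @export
compute_soap <- function(config, params) {
  stopifnot(inherits(config, "configuration"), inherits(params, "soap_params"))
  codes <- species_codes(config, params)
  per_atom <- soap_atoms_cpp(config$positions, codes, soap_spec_cpp(params),
                             if (is.null(config$cell)) NULL else config$cell,
                             config$periodic)
  # global vector: per-centre-species averages concatenated (environments of
  # O-centred and H-centred atoms carry distinct information), then
  # unit-normalized
  n <- nrow(per_atom)
  v <- unlist(lapply(seq_along(params$species) - 1L, function(s) {
    rows <- per_atom[codes == s, , drop = FALSE]
    if (nrow(rows)) colSums(rows) / n else numeric(ncol(per_atom))
  }))
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-300) {
    stop("empty descriptor: no atom has neighbours within r_cut")
  }
  structure(v / nrm, class = "descriptor_vector",
            params_hash = soap_params_hash(params), n_atoms = nrow(per_atom))
}

soap_params_hash <- function(params) {
  paste(c(params$species, params$r_cut, params$n_max, params$l_max,
          params$sigma_atom), collapse = "|")
}

#' Descriptor similarity kernel
#'
#' `kernel(p, q, zeta)` returns `|p . q|^zeta` for two unit-normalized
#' descriptor vectors; it is symmetric, equals 1 for identical vectors, and
#' larger `zeta` sharpens the sensitivity to changes in atomic positions.
#'
#' @param p,q unit-normalized descriptor vectors of equal length.
#' @param zeta positive integer exponent.
#' @return a scalar in `[0, 1]`.
#' @export
soap_kernel <- function(p, q, zeta = 4L) {
  if (length(p) != length(q)) {
    stop("descriptor length mismatch: ", length(p), " vs ", length(q))
  }
  zeta <- as.integer(zeta)
  if (is.na(zeta) || zeta < 1L) stop("zeta must be a positive integer")
  abs(sum(as.numeric(p) * as.numeric(q)))^zeta
}

#' Similarity vector of a candidate against a training set
#'
#' One kernel entry per training descriptor; the selector decision uses the
#' maximum of this vector.
#'
#' @param p0 candidate descriptor vector.
#' @param training list of training descriptor vectors (or a matrix with one
#'   row per member).
#' @param zeta kernel exponent.
#' @return numeric vector `K` with attribute `max` (its maximum).
#' @export
similarity_vector <- function(p0, training, zeta = 4L) {
  M <- as_descriptor_matrix(training)
  if (nrow(M) == 0L) {
    stop("training set is empty: the selector cannot run before initial data exists")
  }
  if (ncol(M) != length(p0)) stop("descriptor length mismatch")
  K <- abs(as.numeric(M %*% as.numeric(p0)))^as.integer(zeta)
  attr(K, "max") <- max(K)
  K
}

as_descriptor_matrix <- function(training) {
  if (is.matrix(training)) return(training)
  if (inherits(training, "descriptor_vector")) training <- list(training)
  if (!length(training)) return(matrix(numeric(0), 0L, 0L))
  do.call(rbind, lapply(training, as.numeric))
}
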