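#' Physical constants and unit conversions
#'
#' Internal units are eV (energy), Angstrom (length), fs (time) and amu
#' (mass). Free energies and model errors are converted to kcal/mol only at
#' reporting boundaries.
#'
#' @format `EV_TO_KCAL_MOL` converts eV to kcal/mol (23.0605); `KB_EV` is
#'   Boltzmann's constant in eV/K; `EVA_AMU_ACC` converts a force/mass ratio
#'   in (eV/A)/amu to an acceleration in A/fs^2; `AMU_A2_FS2_TO_EV` converts
#'   amu A^2 fs^-2 to eV (kinetic energy).
#' @name units
#' @keywords internal
NULL

EV_TO_KCAL_MOL <- 23.0605
KB_EV <- 8.617333262e-5
EVA_AMU_ACC <- 9.64853322e-3
AMU_A2_FS2_TO_EV <- 1 / EVA_AMU_ACC

.ATOMIC_MASSES <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.948,
  K = 39.098, Ca = 40.078, Br = 79.904, I = 126.904
)

# Covalent radii (A), used for distance-based bond perception.
.COVALENT_RADII <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76,
  N = 0.71, O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41,
  Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06,
  K = 2.03, Ca = 1.76, Br = 1.20, I = 1.39
)

#' Look up atomic masses
#'
#' @param species character vector of element symbols.
#' @return numeric vector of masses in amu.
#' @examples
#' atomic_masses(c("O", "H", "H"))
#' @export
atomic_masses <- function(species) {
  m <- .ATOMIC_MASSES[species]
  if (anyNA(m)) {
    stop("unknown element(s): ", paste(unique(species[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

covalent_radii <- function(species) {
  r <- .COVALENT_RADII[species]
  if (anyNA(r)) {
    stop("no covalent radius for element(s): ",
         paste(unique(species[is.na(r)]), collapse = ", "))
  }
  unname(r)
}
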