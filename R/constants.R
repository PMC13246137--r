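#' Physical constants and unit conversion
#'
#' All internal quantities are in Hartree atomic units; geometry input and
#' output use Angstrom. The conversion constant is fixed here and nowhere
#' else.
#'
#' @format Named numeric values.
#' @name constants
NULL

# Angstrom per bohr
ANGSTROM_PER_BOHR <- 0.52917721092

# proton mass in units of the electron mass
PROTON_MASS <- 1836.15267343

angstrom_to_bohr <- function(x) x / ANGSTROM_PER_BOHR
bohr_to_angstrom <- function(x) x * ANGSTROM_PER_BOHR

# element symbol -> nuclear charge, enough for desk-scale fixtures
ELEMENT_Z <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18
)

element_charge <- function(symbol) {
  z <- ELEMENT_Z[symbol]
  if (any(is.na(z))) {
    stop("unknown element symbol: ", paste(symbol[is.na(z)], collapse = ", "))
  }
  unname(z)
}
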