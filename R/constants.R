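#' Physical constants and unit conventions
#'
#' All quantities in this package use a single unit system: energies in
#' electronvolts (eV), distances in angstroms, time in femtoseconds, masses
#' in atomic mass units (amu), and angles in degrees at every user-facing
#' boundary (radians internally). The two conversion constants below are the
#' single source of truth for kinetic-energy and quantum-phase arithmetic.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{ke}{kinetic-energy conversion, 103.6427 eV per amu (angstrom/fs)^2}
#'   \item{hbar}{reduced Planck constant, 0.6582120 eV fs}
#'   \item{kb}{Boltzmann constant, 8.617333e-5 eV/K}
#' }
#' @export
dioxhop_constants <- list(
  ke   = 103.6427,      # 1 amu * (Angstrom/fs)^2 in eV
  hbar = 0.6582120,     # eV * fs
  kb   = 8.617333e-5    # eV / K
)

# internal shorthands
.KE   <- dioxhop_constants$ke
.HBAR <- dioxhop_constants$hbar
.KB   <- dioxhop_constants$kb
.DEG  <- pi / 180
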