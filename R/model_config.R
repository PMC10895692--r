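#' Default model configuration
#'
#' Returns the full default configuration for the analytic model landscape.
#' The model is a reduced-dimensionality surrogate for the singlet/triplet
#' potential-energy surfaces governing dioxetane thermolysis, built from the
#' features that control the dynamics: a C-C Morse well tuned to a ~40 fs
#' vibration, excited-state dissociation ridges near r_CC = 2.16 angstrom,
#' a near-degenerate "entropic trap" window in r_CC, weak singlet-triplet
#' and intra-triplet spin-orbit couplings damped at large separation, and
#' Gaussian-localized nonadiabatic couplings between adjacent states of the
#' same multiplicity and Sz.
#'
#' Coordinates are (r_cc, phi_oocc, phi_cccc, bath_1..bath_m): the C3-C4
#' distance in angstrom, the O1-O2-C3-C4 and C3-C4-C5-C6 dihedral angles in
#' degrees, and m harmonic bath modes in angstrom-like units (default
#' m = 3). Angle "masses" are moments of inertia in amu angstrom^2,
#' converted internally so that velocities are carried in deg/fs.
#'
#' @return a nested named list of model parameters. Fields:
#' \describe{
#'   \item{states}{`n_singlets`, `n_triplets`}
#'   \item{domain}{`r_min`, `r_max` (angstrom): valid r_cc range}
#'   \item{cc}{`mass` (amu, reduced mass of the two fragments), `r_e`
#'     (angstrom, well minimum), `depth` (eV, Morse dissociation energy of
#'     the ground-state channel), `period` (fs, small-amplitude vibration
#'     period of the well)}
#'   \item{ridge}{`height` (eV), `center` (angstrom), `width` (angstrom):
#'     Gaussian barrier added to every excited surface, absent from S0}
#'   \item{offsets}{`singlet`, `triplet`: vertical state offsets (eV)
#'     outside the trap; `trap_lo`, `trap_hi`, `steepness` (angstrom):
#'     logistic window of r_cc inside which the offsets collapse;
#'     `residual`: fraction of the offsets retained inside the trap;
#'     `trap_width` (eV): declared bound on the max pairwise gap at the
#'     trap center}
#'   \item{sz}{`splitting` (eV): energy shift per Sz unit within a triplet;
#'     `epsilon_z` (eV): declared bound on sublevel splitting}
#'   \item{soc}{`singlet_triplet`, `intra_triplet` (eV): coupling
#'     magnitudes; `damp_r`, `damp_width` (angstrom): logistic damping of
#'     all SOC to zero beyond `damp_r`}
#'   \item{dihedrals}{`inertia` (amu angstrom^2), `barrier` (eV),
#'     `reference` (deg): torsional cosine potentials; `q0` (deg): initial
#'     dihedral values}
#'   \item{bath}{`n`, `mass` (amu), `period` (fs): harmonic bath modes}
#'   \item{nac}{`amplitude` (1/angstrom), `center`, `width` (angstrom):
#'     Gaussian NAC magnitude along r_cc between adjacent states of equal
#'     multiplicity and Sz}
#'   \item{coupling}{`phi`, `bath` (eV): strengths of the anharmonic
#'     mode-coupling terms between the C-C stretch and the torsions/bath,
#'     which enable intramolecular vibrational energy redistribution;
#'     `saturation` (1/angstrom): rate at which the coupling saturates
#'     with C-C elongation}
#'   \item{hop_mask}{collapsed labels excluded as hop targets}
#'   \item{q0_r}{initial C-C distance (angstrom)}
#' }
#' @export
default_model_config <- function() {
  list(
    states = list(n_singlets = 4L, n_triplets = 4L),
    domain = list(r_min = 0.9, r_max = 10.0),
    cc = list(mass = 22.0, r_e = 1.60, depth = 1.0, period = 40.0),
    ridge = list(height = 0.5, center = 2.16, width = 0.12),
    offsets = list(
      singlet = c(0.00, 0.30, 0.45, 0.60),
      triplet = c(0.12, 0.35, 1.00, 1.20),
      trap_lo = 1.35, trap_hi = 2.20, steepness = 0.07,
      residual = 0.05, trap_width = 0.20
    ),
    sz = list(splitting = 1e-4, epsilon_z = 1e-3),
    soc = list(singlet_triplet = 0.010, intra_triplet = 0.002,
               damp_r = 3.0, damp_width = 0.10),
    dihedrals = list(inertia = c(5.0, 5.0), barrier = c(0.05, 0.05),
                     reference = c(100.0, 140.0), q0 = c(135.8, 170.0)),
    bath = list(n = 3L, mass = c(1.0, 1.0, 1.0),
                period = c(21.0, 33.0, 47.0)),
    nac = list(amplitude = 1.0, center = 2.16, width = 0.30),
    coupling = list(phi = 0.12, bath = 1.2, saturation = 1.5),
    hop_mask = c("T3", "T4"),
    q0_r = 1.60
  )
}

# Merge a partial configuration over the defaults, rejecting unknown keys.
# `path` accumulates the dotted key path for error messages.
merge_config <- function(defaults, config, path = "") {
  if (is.null(config) || (is.list(config) && length(config) == 0))
    return(defaults)
  if (!is.list(config) || is.null(names(config)) || any(names(config) == ""))
    stop("configuration error: expected a named list at '",
         if (nzchar(path)) path else "<top level>", "'", call. = FALSE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("configuration error: unknown field '",
         paste0(if (nzchar(path)) paste0(path, ".") else "", unknown[1]), "'",
         call. = FALSE)
  out <- defaults
  for (k in names(config)) {
    sub <- paste0(if (nzchar(path)) paste0(path, ".") else "", k)
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      out[[k]] <- merge_config(defaults[[k]], config[[k]], sub)
    } else {
      v <- config[[k]]
      if (is.null(v)) stop("configuration error: missing value for field '",
                           sub, "'", call. = FALSE)
      out[[k]] <- v
    }
  }
  out
}

check_num <- function(x, field, len = NULL, positive = FALSE,
                      nonneg = FALSE) {
  if (!is.numeric(x) || anyNA(x))
    stop("configuration error: field '", field, "' must be numeric",
         call. = FALSE)
  if (!is.null(len) && length(x) != len)
    stop("configuration error: field '", field, "' must have length ", len,
         call. = FALSE)
  if (positive && any(x <= 0))
    stop("configuration error: field '", field, "' must be > 0",
         call. = FALSE)
  if (nonneg && any(x < 0))
    stop("configuration error: field '", field, "' must be >= 0",
         call. = FALSE)
  invisible(x)
}
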