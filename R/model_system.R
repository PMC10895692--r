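#' Wrap angles into the dihedral convention (-180, 180]
#'
#' Dihedral angles live on a circle where -180 degrees equals +180 degrees;
#' this maps any real angle to the representative in (-180, 180].
#'
#' @param x numeric vector of angles in degrees
#' @return wrapped angles in (-180, 180]
#' @export
#' @examples
#' wrap_angle(c(360, -181, 135.8))   # 0, 179, 135.8
wrap_angle <- function(x) {
  x - 360 * ceiling((x - 180) / 360)
}

#' Build an analytic multi-state model system
#'
#' Constructs the surrogate landscape on which the surface-hopping engine
#' runs: per-state potentials V_k(q), the spin-orbit coupling matrix, the
#' nonadiabatic coupling vectors, and the geometric observables. All model
#' surfaces share a Morse well in the C-C distance (the "entropic trap"
#' channel), torsional cosine terms in the two dihedral angles, and the
#' harmonic bath; excited states additionally carry a Gaussian dissociation
#' ridge near the crossing geometry and vertical offsets that collapse
#' inside the trap window, so that the singlet and triplet manifolds are
#' near-degenerate while the C-C bond is intact and split apart once it
#' breaks. The ground singlet has no ridge: a trajectory that dissociates on
#' S0 meets no interior barrier between 2.1 and 2.4 angstrom.
#'
#' @param config a (possibly partial) configuration list; omitted fields
#'   take the values from [default_model_config()]. Unknown fields raise a
#'   configuration error naming the field.
#' @return an object of class `dioxhop_model`: a list with the state table
#'   (`labels`), coordinate names/masses, the initial geometry `q0`, the
#'   reaction-mode unit vector, the callables `mch_potential(q)`, `soc(q)`,
#'   `nac_matrix(q, v)`, `nac_vector(q, a, b)`, `observables(q)`, and the
#'   `hop_mask` index vector.
#' @export
build_model <- function(config = list()) {
  cfg <- merge_config(default_model_config(), config)

  ns <- cfg$states$n_singlets; nt <- cfg$states$n_triplets
  check_num(ns, "states.n_singlets", 1, positive = TRUE)
  check_num(nt, "states.n_triplets", 1, nonneg = TRUE)
  ns <- as.integer(ns); nt <- as.integer(nt)
  check_num(cfg$cc$mass, "cc.mass", 1, positive = TRUE)
  check_num(cfg$cc$depth, "cc.depth", 1, positive = TRUE)
  check_num(cfg$cc$period, "cc.period", 1, positive = TRUE)
  check_num(cfg$ridge$height, "ridge.height", 1)
  if (nt > 0 && cfg$ridge$height <= 0)
    stop("model-construction error: ridge.height must be > 0 so excited ",
         "surfaces have a dissociation ridge", call. = FALSE)
  check_num(cfg$offsets$singlet, "offsets.singlet", ns, nonneg = TRUE)
  check_num(cfg$offsets$triplet, "offsets.triplet", nt, nonneg = TRUE)
  check_num(cfg$soc$singlet_triplet, "soc.singlet_triplet", 1, nonneg = TRUE)
  check_num(cfg$soc$intra_triplet, "soc.intra_triplet", 1, nonneg = TRUE)
  nb <- as.integer(cfg$bath$n)
  check_num(cfg$bath$mass, "bath.mass", nb, positive = TRUE)
  check_num(cfg$bath$period, "bath.period", nb, positive = TRUE)
  check_num(cfg$dihedrals$inertia, "dihedrals.inertia", 2, positive = TRUE)

  labels <- spin_state_labels(ns, nt)
  K <- nrow(labels)

  # Morse stiffness from the requested small-amplitude period:
  # omega = 2*pi/T, k = m_eff * omega^2, a = sqrt(k / (2 De))
  m_r <- cfg$cc$mass * .KE                # eV fs^2 / A^2
  omega_cc <- 2 * pi / cfg$cc$period
  k_cc <- m_r * omega_cc^2
  a_cc <- sqrt(k_cc / (2 * cfg$cc$depth))

  coord_names <- c("r_cc", "phi_oocc", "phi_cccc",
                   if (nb > 0) paste0("bath", seq_len(nb)))
  d <- 3L + nb
  # angle coordinates are carried in degrees: effective mass I*(pi/180)^2
  masses <- c(cfg$cc$mass, cfg$dihedrals$inertia * .DEG^2, cfg$bath$mass)
  names(masses) <- coord_names

  k_bath <- if (nb > 0) cfg$bath$mass * .KE * (2 * pi / cfg$bath$period)^2
            else numeric(0)

  delta <- c(cfg$offsets$singlet, rep(cfg$offsets$triplet, 3))  # per state
  has_ridge <- !(labels$multiplicity == 1L & labels$index == 0L)
  sz_shift <- labels$sz * cfg$sz$splitting

  trap_lo <- cfg$offsets$trap_lo; trap_hi <- cfg$offsets$trap_hi
  trap_s <- cfg$offsets$steepness; trap_res <- cfg$offsets$residual

  morse <- function(r) {
    e <- exp(-a_cc * (r - cfg$cc$r_e))
    cfg$cc$depth * (1 - e)^2
  }
  trap_window <- function(r) {
    stats::plogis((r - trap_lo) / trap_s) * stats::plogis((trap_hi - r) / trap_s)
  }
  offset_factor <- function(r) 1 - (1 - trap_res) * trap_window(r)
  ridge <- function(r) {
    cfg$ridge$height * exp(-(r - cfg$ridge$center)^2 / (2 * cfg$ridge$width^2))
  }

  check_domain <- function(q) {
    if (length(q) != d)
      stop("domain error: configuration must have length ", d, call. = FALSE)
    if (!all(is.finite(q)))
      stop("domain error: non-finite configuration", call. = FALSE)
    if (q[1] < cfg$domain$r_min || q[1] > cfg$domain$r_max)
      stop("domain error: r_cc = ", q[1], " outside [", cfg$domain$r_min,
           ", ", cfg$domain$r_max, "]", call. = FALSE)
    invisible(q)
  }

  # Anharmonic mode coupling: a saturating function of C-C elongation
  # multiplying torsional and bath displacements. Without it the reduced
  # model is separable (no intramolecular vibrational redistribution) and
  # a trapped trajectory could never collect enough C-C energy to escape.
  sat <- function(r) 1 - exp(-cfg$coupling$saturation * (r - cfg$cc$r_e))
  shared_potential <- function(q) {
    v <- morse(q[1]) +
      sum(cfg$dihedrals$barrier *
            (1 - cos((q[2:3] - cfg$dihedrals$reference) * .DEG))) +
      cfg$coupling$phi * sat(q[1]) *
        sum(cos((q[2:3] - cfg$dihedrals$reference) * .DEG))
    if (nb > 0) v <- v + sum(0.5 * k_bath * q[4:d]^2) +
      cfg$coupling$bath * sat(q[1]) * sum(q[4:d])
    v
  }

  mch_potential <- function(q) {
    check_domain(q)
    r <- q[1]
    shared_potential(q) + delta * offset_factor(r) +
      has_ridge * ridge(r) + sz_shift
  }

  # SOC pattern: nonzero only between states of different Sz; imaginary
  # singlet-triplet elements, real intra-triplet Sz-mixing elements.
  soc_pattern <- matrix(0 + 0i, K, K)
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    if (labels$sz[a] == labels$sz[b]) next
    if (labels$multiplicity[a] != labels$multiplicity[b]) {
      soc_pattern[a, b] <- 1i * cfg$soc$singlet_triplet
    } else if (labels$multiplicity[a] == 3L) {
      soc_pattern[a, b] <- cfg$soc$intra_triplet
    }
    soc_pattern[b, a] <- Conj(soc_pattern[a, b])
  }
  soc <- function(q) {
    check_domain(q)
    soc_pattern * stats::plogis((cfg$soc$damp_r - q[1]) / cfg$soc$damp_width)
  }

  # NAC pairs: adjacent indices within a multiplicity and Sz block
  nac_pairs <- which(
    outer(labels$multiplicity, labels$multiplicity, "==") &
      outer(labels$sz, labels$sz, "==") &
      abs(outer(labels$index, labels$index, "-")) == 1 &
      upper.tri(matrix(TRUE, K, K)),
    arr.ind = TRUE
  )
  nac_mag <- function(r) {
    cfg$nac$amplitude * exp(-(r - cfg$nac$center)^2 / (2 * cfg$nac$width^2))
  }
  nac_matrix <- function(q, v) {
    # K x K antisymmetric matrix of v . d_ab (scalar couplings, 1/fs)
    g <- nac_mag(q[1]) * v[1]
    m <- matrix(0, K, K)
    m[nac_pairs] <- g
    m - t(m)
  }
  nac_vector <- function(q, a, b) {
    out <- numeric(d)
    ok <- (labels$multiplicity[a] == labels$multiplicity[b]) &&
      (labels$sz[a] == labels$sz[b]) &&
      abs(labels$index[a] - labels$index[b]) == 1
    if (ok) out[1] <- nac_mag(q[1]) * sign(labels$index[b] - labels$index[a])
    out
  }

  observables <- function(q) {
    check_domain(q)
    list(r_cc = unname(q[1]), phi_oocc = unname(wrap_angle(q[2])),
         phi_cccc = unname(wrap_angle(q[3])))
  }

  q0 <- c(cfg$q0_r, cfg$dihedrals$q0, rep(0, nb))
  names(q0) <- coord_names
  reaction_mode <- c(1, rep(0, d - 1))
  names(reaction_mode) <- coord_names

  hop_mask <- which(labels$collapsed %in% cfg$hop_mask)

  structure(list(
    config = cfg, labels = labels, K = K, d = d,
    coord_names = coord_names, masses = masses, q0 = q0,
    reaction_mode = reaction_mode, hop_mask = hop_mask,
    mch_potential = mch_potential, soc = soc,
    nac_matrix = nac_matrix, nac_vector = nac_vector,
    observables = observables,
    morse_a = a_cc, k_cc = k_cc
  ), class = "dioxhop_model")
}

#' @export
print.dioxhop_model <- function(x, ...) {
  cat("dioxhop model:", x$config$states$n_singlets, "singlets +",
      x$config$states$n_triplets, "triplets (K =", x$K, "MCH states),",
      x$d, "coordinates\n")
  cat("  C-C well: depth", x$config$cc$depth, "eV, period",
      x$config$cc$period, "fs; ridge", x$config$ridge$height, "eV at",
      x$config$ridge$center, "A\n")
  invisible(x)
}

#' Evaluate the total Hamiltonian at a geometry
#'
#' Assembles H_total = H_MCH + H_SOC at configuration `q` and diagonalizes
#' it. H_MCH is diagonal (the spin-free state energies); H_SOC is the
#' Hermitian spin-orbit matrix. The eigenvectors define the "diagonal"
#' representation in which the engine propagates and hops. Eigenvalues are
#' returned in ascending order and each eigenvector's phase is fixed
#' deterministically by making its largest-magnitude component real and
#' positive.
#'
#' @param model a `dioxhop_model`
#' @param q configuration vector (length `model$d`; angles in degrees)
#' @return a list with `h_mch` (length-K energies, eV), `h_soc` (K x K
#'   complex), `h_total`, `u` (K x K unitary, columns are diagonal states),
#'   and `diag_energies` (ascending, eV)
#' @export
evaluate_total_hamiltonian <- function(model, q) {
  e_mch <- model$mch_potential(q)
  h_soc <- model$soc(q)
  h <- h_soc
  diag(h) <- diag(h) + e_mch
  es <- eigen(h, symmetric = TRUE)
  idx <- order(es$values)            # ascending
  vals <- es$values[idx]
  u <- es$vectors[, idx, drop = FALSE]
  u <- fix_phase(u)
  list(h_mch = e_mch, h_soc = h_soc, h_total = h, u = u,
       diag_energies = vals)
}

# Rotate each column so its largest-magnitude component is real positive.
fix_phase <- function(u) {
  for (j in seq_len(ncol(u))) {
    i <- which.max(Mod(u[, j]))
    z <- u[i, j]
    if (Mod(z) > 0) u[, j] <- u[, j] * Conj(z) / Mod(z)
  }
  u
}

#' Geometric observables at a configuration
#'
#' Reports the C3-C4 distance and the two dihedral angles, with angles
#' wrapped into (-180, 180] under the convention that -180 equals +180.
#'
#' @param model a `dioxhop_model`
#' @param q configuration vector
#' @return list with `r_cc` (angstrom), `phi_oocc`, `phi_cccc` (degrees)
#' @export
geometric_observables <- function(model, q) {
  model$observables(q)
}
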