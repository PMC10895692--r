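#' Kinetic energy of a velocity vector
#'
#' @param v velocities (angstrom/fs for distances, deg/fs for angles)
#' @param masses per-coordinate inertial parameters in the model's units
#'   (amu; angle entries already converted per degree^2)
#' @return kinetic energy in eV
#' @export
kinetic_energy <- function(v, masses) {
  0.5 * sum(masses * v^2) * .KE
}

#' Sample Boltzmann-distributed velocities
#'
#' Draws each coordinate's velocity independently from the zero-mean
#' Gaussian with variance kT / m_i, the classical Boltzmann distribution at
#' temperature `temperature`. Uses the current R random stream; seed with
#' `set.seed()` for reproducibility.
#'
#' @param model a `dioxhop_model`
#' @param temperature in kelvin (>= 0); 0 gives exactly zero velocities
#' @return named velocity vector (length `model$d`)
#' @export
sample_boltzmann_velocities <- function(model, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      is.na(temperature) || temperature < 0)
    stop("temperature must be a single number >= 0", call. = FALSE)
  sd <- sqrt(.KB * temperature / (model$masses * .KE))
  v <- stats::rnorm(model$d, mean = 0, sd = sd)
  names(v) <- model$coord_names
  v
}

#' Rescale velocities to an exact kinetic energy
#'
#' Multiplies the whole velocity vector by sqrt(target / KE(input)) so the
#' kinetic energy equals `target` exactly (global rescaling; the direction
#' in velocity space is unchanged).
#'
#' @param v velocity vector
#' @param masses per-coordinate inertial parameters
#' @param target target kinetic energy in eV (> 0)
#' @return rescaled velocity vector with KE equal to `target`
#' @export
rescale_to_energy <- function(v, masses, target) {
  stopifnot(is.numeric(target), length(target) == 1, target > 0)
  ke <- kinetic_energy(v, masses)
  if (ke <= 0)
    stop("degenerate-input error: cannot rescale all-zero velocities",
         call. = FALSE)
  v * sqrt(target / ke)
}

#' Select the forward (product-direction) branch of a velocity sample
#'
#' If the projection of the velocities onto the reaction mode is negative,
#' the component along the mode is reflected (sign-flipped) so the output
#' always points toward products. The reflection is performed in
#' mass-weighted velocity space, so kinetic energy and all orthogonal
#' components are exactly preserved. A numerically zero projection cannot be
#' assigned a direction and raises a resample condition for the caller to
#' redraw.
#'
#' @param v velocity vector
#' @param reaction_mode unit vector defining the product direction
#' @param masses per-coordinate inertial parameters
#' @return velocity vector with strictly positive forward projection
#' @export
select_forward <- function(v, reaction_mode, masses) {
  stopifnot(abs(sum(reaction_mode^2) - 1) < 1e-8)
  w <- sqrt(masses) * v
  uw <- sqrt(masses) * reaction_mode
  uw <- uw / sqrt(sum(uw^2))
  p <- sum(w * uw)
  if (abs(p) < 1e-12)
    stop(structure(class = c("dioxhop_resample", "error", "condition"),
                   list(message = "zero forward projection: redraw",
                        call = NULL)))
  if (p < 0) w <- w - 2 * p * uw
  out <- w / sqrt(masses)
  names(out) <- names(v)
  out
}

#' Initial-velocity features of a trajectory
#'
#' The scalars used later to classify trajectories by product state: the
#' initial angular velocities of the two dihedral angles (omega0_1234 for
#' O1-O2-C3-C4, omega0_3456 for C3-C4-C5-C6, deg/fs) and the bond-rate
#' surrogates v0_34 (the C3-C4 stretch rate) and v0_12, v0_56 (the first
#' two bath modes standing in for the O1-O2 and C5-C6 stretch rates).
#'
#' @param model a `dioxhop_model`
#' @param q0 initial configuration (unused beyond validation; features are
#'   linear in the velocities)
#' @param v0 initial velocity vector
#' @return named list of feature scalars
#' @export
compute_initial_features <- function(model, q0, v0) {
  model$observables(q0)  # domain validation
  list(
    omega0_1234 = unname(v0[2]),
    omega0_3456 = unname(v0[3]),
    v0_34 = unname(v0[1]),
    v0_12 = if (model$d >= 4) unname(v0[4]) else 0,
    v0_56 = if (model$d >= 5) unname(v0[5]) else 0
  )
}

#' Draw one complete set of initial conditions
#'
#' The sampling protocol for every trajectory: all trajectories start from
#' the same geometry (the O-O bond-breaking transition-state surrogate,
#' `model$q0`); velocities are Boltzmann-sampled at `temperature`, globally
#' rescaled to the fixed kinetic energy `target_ke`, and the branch moving
#' forward along the reaction mode is selected. By default a backward sample
#' has its reaction-mode component sign-flipped (preserving the forward
#' marginal); with `method = "reject"` backward samples are redrawn instead.
#'
#' @param model a `dioxhop_model`
#' @param temperature kelvin (default 300)
#' @param target_ke kinetic energy after rescaling, eV (default 3.96)
#' @param seed optional integer seed applied before drawing
#' @param method "flip" (default) or "reject"
#' @return a list of class `dioxhop_initial`: `q0`, `v0`, `kinetic_energy`,
#'   `seed`, `features`
#' @export
sample_initial_conditions <- function(model, temperature = 300,
                                      target_ke = 3.96, seed = NULL,
                                      method = c("flip", "reject")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  repeat {
    v <- sample_boltzmann_velocities(model, temperature)
    if (kinetic_energy(v, model$masses) <= 0) next
    v <- rescale_to_energy(v, model$masses, target_ke)
    if (method == "reject" &&
        sum(sqrt(model$masses) * v *
              sqrt(model$masses) * model$reaction_mode) < 0) next
    v2 <- tryCatch(select_forward(v, model$reaction_mode, model$masses),
                   dioxhop_resample = function(e) NULL)
    if (!is.null(v2)) { v <- v2; break }
  }
  ke <- kinetic_energy(v, model$masses)
  stopifnot(abs(ke - target_ke) < 1e-9)
  structure(list(
    q0 = model$q0, v0 = v, kinetic_energy = ke, seed = seed,
    features = compute_initial_features(model, model$q0, v)
  ), class = "dioxhop_initial")
}
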