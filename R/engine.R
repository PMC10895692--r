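#' Engine parameters for surface-hopping propagation
#'
#' @param dt nuclear time step, fs (default 0.5)
#' @param electronic_substeps electronic substeps per nuclear step
#' @param t_max maximum propagation time, fs
#' @param r_dissoc C-C distance defining bond cleavage, angstrom (2.4; the
#'   product state is labeled at the first sample beyond it)
#' @param r_terminate C-C distance at which the trajectory is stopped (3.7)
#' @param decoherence_constant C of the energy-based decoherence
#'   correction, eV (2.72, i.e. 0.1 hartree)
#' @param energy_drift_tolerance total-energy drift that marks a trajectory
#'   as failed, eV
#' @param fd_step central-difference step for gradients of the diagonal
#'   surfaces (coordinate units)
#' @param temperature sampling temperature, K
#' @param target_ke initial kinetic energy after rescaling, eV
#' @param frustrated_reversal reverse the directed velocity component on a
#'   frustrated hop (default FALSE: reject without reversal)
#' @return a list of class `dioxhop_params`
#' @export
engine_params <- function(dt = 0.5, electronic_substeps = 25, t_max = 2000,
                          r_dissoc = 2.4, r_terminate = 3.7,
                          decoherence_constant = 2.72,
                          energy_drift_tolerance = 0.2, fd_step = 1e-4,
                          temperature = 300, target_ke = 3.96,
                          frustrated_reversal = FALSE) {
  stopifnot(dt > 0, electronic_substeps >= 1, t_max > 0,
            r_terminate > r_dissoc, fd_step > 0)
  structure(list(dt = dt, electronic_substeps = electronic_substeps,
                 t_max = t_max, r_dissoc = r_dissoc,
                 r_terminate = r_terminate,
                 decoherence_constant = decoherence_constant,
                 energy_drift_tolerance = energy_drift_tolerance,
                 fd_step = fd_step, temperature = temperature,
                 target_ke = target_ke,
                 frustrated_reversal = frustrated_reversal),
            class = "dioxhop_params")
}

#' One velocity-Verlet step on the active surface
#'
#' Standard velocity-Verlet update: half-kick, drift, half-kick, using the
#' gradient of the active surface at the start and end geometries.
#'
#' @param q,v configuration and velocity vectors
#' @param grad_fun function(q) returning the gradient (eV per coordinate
#'   unit) of the active surface
#' @param dt time step, fs
#' @param masses per-coordinate inertial parameters
#' @param g0 optional precomputed gradient at `q`
#' @return list with `q`, `v`, and `g` (gradient at the new geometry, for
#'   reuse in the next step)
#' @export
propagate_nuclei <- function(q, v, grad_fun, dt, masses, g0 = NULL) {
  if (is.null(g0)) g0 <- grad_fun(q)
  if (!all(is.finite(g0)))
    stop("propagation error: non-finite gradient", call. = FALSE)
  a0 <- -g0 / (masses * .KE)
  vh <- v + 0.5 * a0 * dt
  q1 <- q + vh * dt
  g1 <- grad_fun(q1)
  if (!all(is.finite(g1)))
    stop("propagation error: non-finite gradient", call. = FALSE)
  v1 <- vh + 0.5 * (-g1 / (masses * .KE)) * dt
  list(q = q1, v = v1, g = g1)
}

# Gradient of the j-th (ascending) eigenvalue of H_total by central
# differences on the analytic surfaces.
diag_surface_gradient <- function(model, q, j, h = 1e-4) {
  g <- numeric(model$d)
  for (i in seq_len(model$d)) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    ep <- eigenvalues_total(model, qp)[j]
    em <- eigenvalues_total(model, qm)[j]
    g[i] <- (ep - em) / (2 * h)
  }
  g
}

eigenvalues_total <- function(model, q) {
  h <- model$soc(q)
  diag(h) <- diag(h) + model$mch_potential(q)
  sort(eigen(h, symmetric = TRUE, only.values = TRUE)$values)
}

# Align a new eigenvector frame to the previous one: greedy column matching
# on |overlap| (preventing spurious state relabeling through trivial
# crossings), then phase-fix so the diagonal overlap is real positive.
align_frames <- function(u_prev, u_new, e_new) {
  K <- ncol(u_new)
  ov <- Mod(Conj(t(u_prev)) %*% u_new)   # |<old_i | new_j>|
  perm <- integer(K)
  used <- rep(FALSE, K)
  for (rep_i in seq_len(K)) {
    idx <- which(ov == max(ov), arr.ind = TRUE)[1, ]
    perm[idx[1]] <- idx[2]
    ov[idx[1], ] <- -1
    ov[, idx[2]] <- -1
  }
  u <- u_new[, perm, drop = FALSE]
  e <- e_new[perm]
  ph <- diag(Conj(t(u_prev)) %*% u)
  ph <- ifelse(Mod(ph) > 0, Conj(ph) / Mod(ph), 1)
  u <- sweep(u, 2, ph, "*")
  list(u = u, e = e)
}

# Loewdin orthonormalization of a near-unitary overlap matrix.
orthonormalize <- function(s) {
  sv <- svd(s)
  sv$u %*% Conj(t(sv$v))
}

# Velocity adjustment for a hop: rescale the component along `dir` so total
# energy is conserved; insufficient directed kinetic energy frustrates the
# hop. Returns list(accepted, v, used_velocity_fallback).
hop_rescale <- function(v, dir, masses, de, frustrated_reversal = FALSE) {
  fallback <- FALSE
  if (sqrt(sum(dir^2)) < 1e-12) { dir <- v; fallback <- TRUE }
  nrm <- sqrt(sum(dir^2))
  if (nrm < 1e-12) return(list(accepted = FALSE, v = v, fallback = fallback))
  u <- dir / nrm
  A <- 0.5 * sum(masses * u^2) * .KE
  B <- sum(masses * v * u) * .KE
  disc <- B^2 - 4 * A * de
  if (disc < 0) {
    if (frustrated_reversal) {
      p <- sum(masses * v * u) / sum(masses * u^2)
      v <- v - 2 * p * u
    }
    return(list(accepted = FALSE, v = v, fallback = fallback))
  }
  g1 <- (-B + sqrt(disc)) / (2 * A)
  g2 <- (-B - sqrt(disc)) / (2 * A)
  gamma <- if (abs(g1) <= abs(g2)) g1 else g2
  list(accepted = TRUE, v = v + gamma * u, fallback = fallback)
}

#' Attempt a surface hop with momentum adjustment
#'
#' Rescales the velocity component along the projected coupling direction
#' so that total energy is conserved exactly across the hop. If the kinetic
#' energy along that direction cannot cover the potential-energy gap the
#' hop is frustrated: the active state and (by default) the velocities are
#' unchanged. A zero coupling direction falls back to rescaling along the
#' full velocity vector.
#'
#' @param v velocity vector
#' @param direction rescaling direction (the nonadiabatic coupling vector
#'   between the states' dominant characters, or zero to force the
#'   velocity-vector fallback)
#' @param masses per-coordinate inertial parameters
#' @param de potential-energy change E_target - E_active (eV)
#' @param frustrated_reversal reverse the directed component when
#'   frustrated
#' @return list with `accepted`, `v`, `fallback`
#' @export
attempt_hop <- function(v, direction, masses, de,
                        frustrated_reversal = FALSE) {
  hop_rescale(v, direction, masses, de, frustrated_reversal)
}

#' Run one surface-hopping trajectory
#'
#' Propagates nuclei by velocity-Verlet on the active diagonal surface and
#' the electronic coefficients by sub-stepped unitary evolution in the
#' diagonal basis, with fewest-switches hops, exact energy conservation at
#' accepted hops, energy-based decoherence, and the termination protocol:
#' the dissociation time is the first sample with r_CC above `r_dissoc`
#' (2.4 angstrom), where the product MCH label is frozen; the run ends when
#' r_CC exceeds `r_terminate` (3.7 angstrom), when `t_max` is reached, or
#' when the total energy drifts beyond tolerance (status `failed_energy`).
#' After the bond cleaves, hops among Sz sublevels may continue; a change
#' of the collapsed label is recorded in `label_drift` (asserted absent in
#' the ensemble tests, not enforced).
#'
#' @param model a `dioxhop_model`
#' @param initial a `dioxhop_initial` (or list with `q0`, `v0`)
#' @param params a `dioxhop_params`
#' @return an object of class `dioxhop_trajectory`: list with `steps`
#'   (data.frame), `hops` (data.frame), `status` ("dissociated",
#'   "timed_out" or "failed_energy"), `product_mch`, `product_collapsed`,
#'   `dissociation_time`, `label_drift`, `initial`
#' @export
run_trajectory <- function(model, initial, params = engine_params()) {
  dt <- params$dt
  n_max <- ceiling(params$t_max / dt)
  d <- model$d; K <- model$K
  masses <- model$masses
  labels <- model$labels

  q <- as.numeric(initial$q0); v <- as.numeric(initial$v0)
  ham <- evaluate_total_hamiltonian(model, q)
  U <- ham$u; E <- ham$diag_energies
  s0_idx <- which(labels$multiplicity == 1L & labels$index == 0L)
  active <- which.max(Mod(U[s0_idx, ])^2)
  coeffs <- rep(0 + 0i, K); coeffs[active] <- 1

  mch_of <- function(u, j) which.max(Mod(u[, j])^2)
  e_total0 <- kinetic_energy(v, masses) + E[active]

  # preallocated step storage
  nr <- n_max + 1
  S_t <- numeric(nr); S_r <- numeric(nr)
  S_p1 <- numeric(nr); S_p2 <- numeric(nr)
  S_ad <- integer(nr); S_am <- integer(nr)
  S_ea <- numeric(nr); S_et <- numeric(nr)
  S_q <- matrix(NA_real_, nr, d); S_v <- matrix(NA_real_, nr, d)
  hops <- list()

  obs <- model$observables(q)
  S_t[1] <- 0; S_r[1] <- obs$r_cc; S_p1[1] <- obs$phi_oocc
  S_p2[1] <- obs$phi_cccc; S_ad[1] <- active
  S_am[1] <- mch_of(U, active); S_ea[1] <- E[active]; S_et[1] <- e_total0
  S_q[1, ] <- q; S_v[1, ] <- v

  status <- "timed_out"
  dissociation_time <- NA_real_
  product_mch_idx <- NA_integer_
  label_drift <- FALSE
  g_cache <- NULL
  n_rec <- 1

  run_loop <- function() {
    for (step in seq_len(n_max)) {
      t_now <- step * dt
      asc_j <- sum(E <= E[active] + 1e-15)   # ascending rank of active
      grad_fun <- function(qq) diag_surface_gradient(model, qq, asc_j,
                                                     params$fd_step)
      nuc <- propagate_nuclei(q, v, grad_fun, dt, masses, g_cache)
      q1 <- nuc$q; v1 <- nuc$v

      ham1 <- evaluate_total_hamiltonian(model, q1)
      fr <- align_frames(U, ham1$u, ham1$diag_energies)
      U1 <- fr$u; E1 <- fr$e

      S <- orthonormalize(Conj(t(U)) %*% U1)
      T_ov <- (S - Conj(t(S))) / (2 * dt)
      D <- model$nac_matrix(q1, v1)
      T_nac <- Conj(t(U1)) %*% D %*% U1
      Tm <- T_ov + T_nac
      coupling <- -1i * .HBAR * Tm
      h0 <- coupling; diag(h0) <- diag(h0) + E
      h1 <- coupling; diag(h1) <- diag(h1) + E1
      coeffs <<- propagate_electronic(coeffs, h0, h1, dt,
                                      params$electronic_substeps)

      # hop decision
      mask <- which(apply(Mod(U1)^2, 2, which.max) %in% model$hop_mask)
      g <- hop_probabilities(coeffs, (h0 + h1) / 2, active, dt, mask)
      zeta <- stats::runif(1)
      cg <- cumsum(g)
      target <- if (zeta < cg[K]) which(zeta < cg)[1] else 0L
      hopped <- FALSE
      if (target > 0 && target != active) {
        a_mch <- mch_of(U1, active); t_mch <- mch_of(U1, target)
        dir <- model$nac_vector(q1, a_mch, t_mch)
        res <- attempt_hop(v1, dir, masses, E1[target] - E1[active],
                           params$frustrated_reversal)
        hops[[length(hops) + 1]] <<- list(
          t = t_now, from_diag = active, to_diag = target,
          from_mch = labels$name[a_mch], to_mch = labels$name[t_mch],
          frustrated = !res$accepted, velocity_fallback = res$fallback)
        if (res$accepted) {
          v1 <- res$v
          active <<- target
          hopped <- TRUE
        } else if (params$frustrated_reversal) {
          v1 <- res$v
          hopped <- TRUE   # gradient cache invalid after velocity reversal
        }
      }
      ek <- kinetic_energy(v1, masses)
      coeffs <<- apply_decoherence(coeffs, E1, active, ek, dt,
                                   params$decoherence_constant)

      obs <- model$observables(q1)
      e_tot <- ek + E1[active]
      i <- step + 1
      S_t[i] <<- t_now; S_r[i] <<- obs$r_cc
      S_p1[i] <<- obs$phi_oocc; S_p2[i] <<- obs$phi_cccc
      S_ad[i] <<- active; S_am[i] <<- mch_of(U1, active)
      S_ea[i] <<- E1[active]; S_et[i] <<- e_tot
      S_q[i, ] <<- q1; S_v[i, ] <<- v1
      n_rec <<- i

      if (is.na(dissociation_time) && obs$r_cc > params$r_dissoc) {
        dissociation_time <<- t_now
        product_mch_idx <<- mch_of(U1, active)
      }
      if (!is.na(dissociation_time)) {
        cur <- labels$collapsed[mch_of(U1, active)]
        if (cur != labels$collapsed[product_mch_idx]) label_drift <<- TRUE
      }

      if (abs(e_tot - e_total0) > params$energy_drift_tolerance) {
        status <<- "failed_energy"; return(invisible())
      }
      if (obs$r_cc > params$r_terminate) {
        if (is.na(dissociation_time)) {   # jumped both thresholds at once
          dissociation_time <<- t_now
          product_mch_idx <<- mch_of(U1, active)
        }
        status <<- "dissociated"; return(invisible())
      }

      q <<- q1; v <<- v1; U <<- U1; E <<- E1
      g_cache <<- if (hopped) NULL else nuc$g
    }
    status <<- "timed_out"
    invisible()
  }
  ok <- tryCatch({ run_loop(); TRUE },
                 error = function(e) { status <<- "failed_energy"; FALSE })

  idx <- seq_len(n_rec)
  steps <- data.frame(
    t = S_t[idx], r_cc = S_r[idx], phi_oocc = S_p1[idx],
    phi_cccc = S_p2[idx], active_diag = S_ad[idx],
    active_mch = labels$name[S_am[idx]],
    e_active = S_ea[idx], e_total = S_et[idx]
  )
  qdf <- as.data.frame(S_q[idx, , drop = FALSE])
  names(qdf) <- paste0("q_", model$coord_names)
  vdf <- as.data.frame(S_v[idx, , drop = FALSE])
  names(vdf) <- paste0("v_", model$coord_names)
  steps <- cbind(steps, qdf, vdf)

  hops_df <- if (length(hops) > 0)
    do.call(rbind, lapply(hops, as.data.frame))
  else data.frame(t = numeric(0), from_diag = integer(0),
                  to_diag = integer(0), from_mch = character(0),
                  to_mch = character(0), frustrated = logical(0),
                  velocity_fallback = logical(0))

  structure(list(
    steps = steps, hops = hops_df, status = status,
    product_mch = if (is.na(product_mch_idx)) NA_character_
                  else labels$name[product_mch_idx],
    product_collapsed = if (is.na(product_mch_idx)) NA_character_
                        else labels$collapsed[product_mch_idx],
    dissociation_time = dissociation_time,
    label_drift = label_drift, dt = dt,
    initial = initial
  ), class = "dioxhop_trajectory")
}

#' @export
print.dioxhop_trajectory <- function(x, ...) {
  cat("dioxhop trajectory:", nrow(x$steps), "steps,", x$status)
  if (!is.na(x$dissociation_time))
    cat("; dissociated at", x$dissociation_time, "fs in",
        x$product_collapsed)
  cat("\n")
  invisible(x)
}

# Deterministic per-trajectory seed derived from the master seed.
per_trajectory_seed <- function(master_seed, i) {
  as.integer((as.double(master_seed) %% 2147483647 * 48271 +
                i * 104729) %% 2147483647)
}

#' Run an ensemble of surface-hopping trajectories
#'
#' Each trajectory gets a seed derived deterministically from
#' `master_seed`, controlling both its Boltzmann velocity sample and its
#' hopping random stream, so the whole ensemble is reproducible from
#' (master_seed, model, params) alone. Failures are recorded per trajectory
#' and never abort the ensemble.
#'
#' @param model a `dioxhop_model`
#' @param n number of trajectories (>= 1)
#' @param params a `dioxhop_params`
#' @param master_seed integer master seed
#' @param progress print one line per trajectory
#' @return list of `dioxhop_trajectory`, class `dioxhop_ensemble`
#' @export
run_ensemble <- function(model, n, params = engine_params(), master_seed = 1,
                         progress = FALSE) {
  stopifnot(n >= 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- per_trajectory_seed(master_seed, i)
    ic <- sample_initial_conditions(model, params$temperature,
                                    params$target_ke, seed = seed_i)
    out[[i]] <- run_trajectory(model, ic, params)
    if (progress)
      message(sprintf("trajectory %d/%d: %s%s", i, n, out[[i]]$status,
                      if (!is.na(out[[i]]$dissociation_time))
                        sprintf(" (t_d = %.1f fs, %s)",
                                out[[i]]$dissociation_time,
                                out[[i]]$product_collapsed) else ""))
  }
  structure(out, class = "dioxhop_ensemble", master_seed = master_seed)
}
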