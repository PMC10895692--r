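# Electronic coefficient propagation, hop probabilities and decoherence.
#
# The engine works in the diagonal representation: the effective electronic
# Hamiltonian over a nuclear step is H(tau) = diag(E(tau)) - i*hbar*T, where
# E interpolates linearly between the step endpoints and T collects the
# time-derivative couplings (eigenvector-overlap term plus the transformed
# nonadiabatic-coupling term). H is Hermitian, so every propagation path
# below is exactly unitary.

expm_unitary <- function(h, dt, hbar = .HBAR) {
  # exp(-i h dt / hbar) for Hermitian h
  es <- eigen(h, symmetric = TRUE)
  ph <- exp(-1i * es$values * dt / hbar)
  es$vectors %*% (ph * Conj(t(es$vectors)))
}

#' Propagate electronic coefficients across one nuclear step
#'
#' Advances the coefficient vector under the linearly interpolated
#' Hermitian Hamiltonian H(tau) = (1 - tau) H_start + tau H_end by
#' sub-stepped unitary exponentials. Three cases are handled: a constant
#' Hamiltonian is propagated exactly by a single eigendecomposition; when
#' only the diagonal changes across the step (the engine's situation, since
#' the coupling term is fixed over a nuclear step) a Strang splitting with a
#' precomputed off-diagonal exponential is used; otherwise each substep
#' applies the exponential of the midpoint Hamiltonian. The norm is
#' preserved to machine precision in every case.
#'
#' @param coeffs complex coefficient vector, normalized within 1e-6
#' @param h_start,h_end K x K Hermitian matrices (eV); any anti-Hermitian
#'   coupling T enters as the Hermitian block -i*hbar*T
#' @param dt nuclear step (fs)
#' @param substeps number of electronic substeps (>= 1)
#' @return the advanced coefficient vector
#' @export
propagate_electronic <- function(coeffs, h_start, h_end, dt, substeps = 25) {
  stopifnot(substeps >= 1, dt > 0)
  n0 <- sum(Mod(coeffs)^2)
  if (abs(n0 - 1) > 1e-6)
    stop("numerical error: coefficient norm ", format(n0),
         " on entry", call. = FALSE)
  dh <- h_end - h_start
  delta <- dt / substeps
  if (max(Mod(dh)) < 1e-14) {
    coeffs <- as.vector(expm_unitary(h_start, dt) %*% coeffs)
  } else {
    off <- dh; diag(off) <- 0
    if (max(Mod(off)) < 1e-14) {
      # constant off-diagonal block: Strang split diag/off-diag
      a <- h_start; diag(a) <- 0
      w <- expm_unitary(a, delta)
      d0 <- Re(diag(h_start)); d1 <- Re(diag(h_end))
      for (j in seq_len(substeps)) {
        dm <- d0 + (j - 0.5) / substeps * (d1 - d0)
        half <- exp(-1i * dm * delta / (2 * .HBAR))
        coeffs <- half * as.vector(w %*% (half * coeffs))
      }
    } else {
      for (j in seq_len(substeps)) {
        hm <- h_start + (j - 0.5) / substeps * dh
        coeffs <- as.vector(expm_unitary(hm, delta) %*% coeffs)
      }
    }
  }
  n1 <- sum(Mod(coeffs)^2)
  if (abs(n1 - 1) > 1e-6)
    stop("numerical error: norm drift ", format(abs(n1 - 1)), call. = FALSE)
  coeffs
}

#' Fewest-switches hop probabilities
#'
#' Tully's prescription: the probability of switching from the active state
#' a to state k over a step is the positive part of the population flux from
#' a to k, times dt, divided by the active population. With the Hermitian
#' effective Hamiltonian H the flux out of a toward k is
#' -(2/hbar) Im(conj(c_a) H_ak c_k). Masked target states (e.g. the T3/T4
#' sublevels, to which hopping is turned off) are forced to zero. If the
#' probabilities sum above 1 they are rescaled to sum to 1.
#'
#' @param coeffs complex coefficients
#' @param h_eff Hermitian effective Hamiltonian for the step (eV)
#' @param active index of the active state
#' @param dt step size (fs)
#' @param mask optional indices whose probability is forced to zero
#' @return probability vector (zero at the active index)
#' @export
hop_probabilities <- function(coeffs, h_eff, active, dt, mask = integer(0)) {
  pa <- Mod(coeffs[active])^2
  if (pa <= 0)
    stop("degenerate-state error: active population is zero", call. = FALSE)
  flux <- -(2 / .HBAR) *
    Im(Conj(coeffs[active]) * h_eff[active, ] * coeffs)
  g <- pmax(0, flux * dt / pa)
  g[active] <- 0
  g[mask] <- 0
  s <- sum(g)
  if (s > 1) g <- g / s
  g
}

#' Energy-based decoherence correction
#'
#' Damps every non-active amplitude by exp(-dt/tau_k) with
#' tau_k = (hbar / |E_k - E_active|) * (1 + C / E_kin), then rescales the
#' active amplitude to restore unit norm. States degenerate with the active
#' one (or a non-positive kinetic energy) give an infinite decoherence time
#' and are left untouched.
#'
#' @param coeffs complex coefficients (unit norm)
#' @param diag_energies state energies (eV)
#' @param active active-state index
#' @param e_kin nuclear kinetic energy (eV)
#' @param dt step size (fs)
#' @param C decoherence constant in eV (default 2.72, i.e. 0.1 hartree)
#' @return damped, renormalized coefficient vector
#' @export
apply_decoherence <- function(coeffs, diag_energies, active, e_kin, dt,
                              C = 2.72) {
  if (e_kin <= 0) return(coeffs)
  gap <- abs(diag_energies - diag_energies[active])
  damp <- ifelse(gap > 0, exp(-dt * gap / (.HBAR * (1 + C / e_kin))), 1)
  damp[active] <- 1
  out <- coeffs * damp
  rest <- sum(Mod(out[-active])^2)
  pa <- Mod(out[active])^2
  if (pa > 0) out[active] <- out[active] * sqrt(max(0, 1 - rest) / pa)
  out
}
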