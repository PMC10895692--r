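#' Dissociation time of a trajectory
#'
#' The time of the first recorded sample whose C-C distance exceeds
#' `r_dissoc` ("it just becomes greater than 2.4 angstrom"): strictly
#' greater than, no interpolation between samples, so times are quantized
#' to the step size.
#'
#' @param record a `dioxhop_trajectory`, or a list with a `steps`
#'   data.frame carrying `t` and `r_cc`
#' @param r_dissoc dissociation distance, angstrom (default 2.4)
#' @return time in fs, or NA if the distance never crosses
#' @export
dissociation_time <- function(record, r_dissoc = 2.4) {
  s <- record$steps
  stopifnot(nrow(s) >= 1)
  i <- which(s$r_cc > r_dissoc)
  if (length(i) == 0) NA_real_ else s$t[i[1]]
}

#' Product state of a dissociated trajectory
#'
#' The MCH label active at the first sample beyond `r_dissoc`, with triplet
#' Sz sublevels collapsed to the parent triplet (T1,-1 / T1,0 / T1,1 are
#' all termed T1). The label is frozen at bond cleavage even though Sz hops
#' may continue afterwards.
#'
#' @inheritParams dissociation_time
#' @return collapsed label, e.g. "S0" or "T1"
#' @export
product_state_label <- function(record, r_dissoc = 2.4) {
  s <- record$steps
  i <- which(s$r_cc > r_dissoc)
  if (length(i) == 0)
    stop("undefined-product error: trajectory never dissociated",
         call. = FALSE)
  collapse_label(s$active_mch[i[1]])
}

#' Count frustrated dissociations in a C-C distance series
#'
#' A frustrated dissociation is an aborted bond-breaking attempt, visible
#' as a local maximum in the time evolution of the C-C distance. Counts the
#' interior strict local maxima with topographic prominence at least
#' `min_prominence` (default 0.05 angstrom, suppressing integrator jitter);
#' the counting window ends at `end_index` (e.g. the final crossing of the
#' dissociation distance) so peaks after dissociation are excluded.
#'
#' @param r numeric series of C-C distances
#' @param min_prominence minimum peak prominence, angstrom
#' @param end_index last index of the counting window (default: whole
#'   series)
#' @return integer number of peaks
#' @export
count_frustrated_dissociations <- function(r, min_prominence = 0.05,
                                           end_index = length(r)) {
  r <- r[seq_len(min(end_index, length(r)))]
  n <- length(r)
  if (n < 3) return(0L)
  peaks <- which(r[2:(n - 1)] > r[1:(n - 2)] & r[2:(n - 1)] > r[3:n]) + 1L
  if (length(peaks) == 0) return(0L)
  keep <- vapply(peaks, function(p) {
    peak_prominence(r, p) >= min_prominence
  }, logical(1))
  sum(keep)
}

# Topographic prominence of the peak at index p: on each side, the lowest
# value between the peak and the nearest strictly higher sample (or the
# series end); prominence is peak height minus the larger of the two bases.
peak_prominence <- function(r, p) {
  h <- r[p]
  left <- if (p == 1) h else {
    seg <- r[(p - 1):1]
    hi <- which(seg > h)
    base <- if (length(hi) > 0) min(seg[1:hi[1]]) else min(seg)
    base
  }
  right <- if (p == length(r)) h else {
    seg <- r[(p + 1):length(r)]
    hi <- which(seg > h)
    base <- if (length(hi) > 0) min(seg[1:hi[1]]) else min(seg)
    base
  }
  h - max(left, right)
}

#' Mean C-C oscillation period from a peak count
#'
#' The window length divided by the number of frustrated-dissociation peaks
#' within it, e.g. 975.5 fs / 24 peaks = 40.6 fs.
#'
#' @param n_peaks number of peaks (>= 1 for a defined period)
#' @param window window length, fs
#' @return period in fs, or NA if `n_peaks` is 0
#' @export
mean_oscillation_period <- function(n_peaks, window) {
  if (n_peaks == 0) return(NA_real_)
  window / n_peaks
}

#' Transition-count matrix of an MCH state series
#'
#' Tabulates the K x K matrix of step-to-step transitions of the active MCH
#' state: the diagonal counts steps within a state (step i to step i+1 in
#' the same state is one transition), off-diagonal entries count hops from
#' the row state to the column state. The sum of all entries is the number
#' of samples minus one. Label order is the documented block order (see
#' [spin_state_labels()]).
#'
#' @param series character vector of per-step MCH state names (length >= 2)
#' @param labels optional label vocabulary (character); defaults to the
#'   sorted unique labels of a 4-singlet/4-triplet model restricted to the
#'   labels present
#' @param dt step size in fs (default 0.5), stored for residence times
#' @return a list of class `dioxhop_tcm` with `labels`, `counts` (K x K
#'   integer matrix) and `dt`
#' @export
transition_count_matrix <- function(series, labels = NULL, dt = 0.5) {
  stopifnot(length(series) >= 2)
  if (is.null(labels)) {
    vocab <- spin_state_labels(4, 4)$name
    labels <- vocab[vocab %in% unique(series)]
    if (!all(series %in% vocab))
      labels <- unique(series)
  }
  if (!all(series %in% labels))
    stop("data error: unknown state label '",
         setdiff(series, labels)[1], "'", call. = FALSE)
  K <- length(labels)
  counts <- matrix(0L, K, K, dimnames = list(labels, labels))
  from <- match(series[-length(series)], labels)
  to <- match(series[-1], labels)
  for (i in seq_along(from))
    counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  structure(list(labels = labels, counts = counts, dt = dt),
            class = "dioxhop_tcm")
}

#' @export
print.dioxhop_tcm <- function(x, ...) {
  cat("transition-count matrix (", sum(x$counts), " transitions, dt = ",
      x$dt, " fs)\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Residence times from a transition-count matrix
#'
#' The total steps spent in a state are its diagonal element plus the sum
#' of the off-diagonal elements in its column (hops from all other states
#' into it: the destination convention, under which the first sample of the
#' trajectory is attributed to no state, so the residence times sum to
#' (samples - 1) times dt). Times are steps times `dt`; triplet sublevel
#' columns are additionally summed into collapsed totals.
#'
#' @param tcm a `dioxhop_tcm`
#' @return list with `per_state` (named fs vector), `collapsed` (named fs
#'   vector over Sz-free labels) and `total` (fs)
#' @export
residence_times <- function(tcm) {
  m <- tcm$counts
  steps <- diag(m) + (colSums(m) - diag(m))
  per_state <- steps * tcm$dt
  names(per_state) <- tcm$labels
  coll <- c(tapply(per_state, collapse_label(tcm$labels), sum))
  coll <- coll[unique(collapse_label(tcm$labels))]
  list(per_state = per_state, collapsed = coll, total = sum(per_state))
}

#' Unwrap a wrapped dihedral-angle series
#'
#' Lifts a series of angles from the wrapped representation (-180, 180],
#' where -180 equals +180 and a jump from 178 to -177 is geometrically
#' continuous, to a continuous real-valued path: successive differences of
#' the output lie in (-180, 180] and the output is congruent to the input
#' modulo 360.
#'
#' @param phi numeric series of angles in degrees
#' @return unwrapped series (same length, starts at `phi[1]`)
#' @export
unwrap_dihedral <- function(phi) {
  if (length(phi) <= 1) return(phi)
  d <- diff(phi)
  d <- d - 360 * ceiling((d - 180) / 360)   # representative in (-180, 180]
  cumsum(c(phi[1], d))
}

#' Total dihedral-angle variation along a trajectory
#'
#' The absolute difference between the unwrapped final and initial angles:
#' e.g. the waypoint sequence 135.8 -> 180(-180) -> -90 -> 0 -> 32.9
#' unwraps to 135.8 ... 392.9, a variation of 257.1 degrees.
#'
#' @param phi series or waypoint sequence of wrapped angles, degrees
#' @return variation in degrees
#' @export
angle_variation <- function(phi) {
  stopifnot(length(phi) >= 2)
  u <- unwrap_dihedral(phi)
  abs(u[length(u)] - u[1])
}

#' Per-trajectory summary statistics
#'
#' Bundles the scalar statistics of one trajectory record: dissociation
#' time and collapsed product label, frustrated-dissociation count and
#' mean oscillation period (within the window ending at the final crossing
#' of `r_dissoc`), residence times from the MCH series, total dihedral
#' variation and the initial-velocity features.
#'
#' @param record a `dioxhop_trajectory`
#' @param r_dissoc dissociation distance (angstrom)
#' @param min_prominence peak prominence for frustrated dissociations
#' @return a list of class `dioxhop_summary`
#' @export
summarize_trajectory <- function(record, r_dissoc = 2.4,
                                 min_prominence = 0.05) {
  s <- record$steps
  td <- dissociation_time(record, r_dissoc)
  cross <- which(s$r_cc > r_dissoc)
  end_idx <- if (length(cross) > 0) cross[1] else nrow(s)
  nf <- count_frustrated_dissociations(s$r_cc, min_prominence, end_idx)
  window <- s$t[end_idx] - s$t[1]
  tcm <- transition_count_matrix(s$active_mch, dt = record$dt)
  res <- residence_times(tcm)
  list(
    dissociation_time = td,
    product = if (!is.na(td)) collapse_label(s$active_mch[cross[1]])
              else NA_character_,
    status = record$status,
    n_frustrated = nf,
    mean_period = mean_oscillation_period(nf, window),
    residence = res$collapsed,
    angle_variation = angle_variation(s$phi_oocc),
    n_hops = if (nrow(record$hops) > 0) sum(!record$hops$frustrated) else 0L,
    n_frustrated_hops = if (nrow(record$hops) > 0)
      sum(record$hops$frustrated) else 0L,
    features = if (!is.null(record$initial$features))
      record$initial$features else NULL
  )
}
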