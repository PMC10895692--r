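#' Assemble ensemble-level results
#'
#' Splits an ensemble into completed and failed trajectories and attaches
#' per-trajectory summaries for the completed ones (a failed trajectory
#' contributes only to the failure count, matching the convention that
#' yields and half-times are taken over successfully terminated
#' trajectories).
#'
#' @param ensemble a `dioxhop_ensemble` (list of trajectories)
#' @param r_dissoc dissociation distance, angstrom
#' @return a list of class `dioxhop_ensemble_result` with `summaries`,
#'   `n_launched`, `n_completed`, `n_failed`, `dt`
#' @export
ensemble_result <- function(ensemble, r_dissoc = 2.4) {
  failed <- vapply(ensemble, function(x) x$status == "failed_energy",
                   logical(1))
  completed <- ensemble[!failed]
  summaries <- lapply(completed, summarize_trajectory, r_dissoc = r_dissoc)
  structure(list(
    summaries = summaries,
    n_launched = length(ensemble),
    n_completed = length(completed),
    n_failed = sum(failed),
    dt = if (length(ensemble) > 0) ensemble[[1]]$dt else NA_real_
  ), class = "dioxhop_ensemble_result")
}

#' Chemiexcitation quantum yields
#'
#' The yield of a product state is 100 times the number of completed
#' trajectories ending in that state divided by the number of completed
#' trajectories; yields over the observed labels sum to 100 within
#' rounding.
#'
#' @param product_labels character vector of product-state labels (one per
#'   dissociated trajectory), or a named count vector
#' @param n_completed total completed trajectories (denominator)
#' @return named numeric vector of percentages
#' @export
quantum_yields <- function(product_labels, n_completed) {
  if (n_completed < 1)
    stop("undefined error: no completed trajectories", call. = FALSE)
  counts <- if (is.numeric(product_labels)) product_labels
            else table(product_labels)
  out <- 100 * as.numeric(counts) / n_completed
  names(out) <- names(counts)
  out
}

#' Dissociation half-time
#'
#' The time required for half of the trajectories to dissociate: the
#' sample median of the dissociation times, with the even-count convention
#' of the midpoint of the two central order statistics (which is how
#' quarter-femtosecond half-times arise from half-femtosecond-quantized
#' dissociation times).
#'
#' @param times numeric vector of dissociation times, fs (NAs dropped)
#' @return half-time in fs
#' @export
dissociation_half_time <- function(times) {
  times <- times[is.finite(times)]
  if (length(times) == 0)
    stop("undefined error: no finite dissociation times", call. = FALSE)
  stats::median(times)
}

#' Ensemble-averaged state populations over time
#'
#' At each grid time the population of a state is the fraction of
#' trajectories whose active state maps to it; a trajectory that has
#' already terminated stays frozen at its product label (collapsed for
#' triplets in the collapsed basis; the last Sz sublevel in the full MCH
#' basis; the last diagonal index in the diagonal basis). Fractions sum to
#' one at every time.
#'
#' @param ensemble list of `dioxhop_trajectory` (completed)
#' @param basis "mch_collapsed", "mch_full", or "diagonal"
#' @param t_grid numeric vector of times, fs
#' @return matrix (length(t_grid) x states) of fractions, with a `t`
#'   attribute; column names are state labels
#' @export
population_time_series <- function(ensemble,
                                   basis = c("mch_collapsed", "mch_full",
                                             "diagonal"),
                                   t_grid) {
  basis <- match.arg(basis)
  if (length(t_grid) == 0) stop("empty time grid", call. = FALSE)
  stopifnot(length(ensemble) >= 1)
  state_of <- function(traj) {
    s <- traj$steps
    lab <- switch(basis,
                  mch_collapsed = collapse_label(s$active_mch),
                  mch_full = s$active_mch,
                  diagonal = paste0("D", s$active_diag))
    # post-termination freeze at the final (product) label
    idx <- findInterval(t_grid, s$t)
    idx[idx < 1] <- 1
    lab[idx]
  }
  per_traj <- vapply(ensemble, state_of, character(length(t_grid)))
  if (length(t_grid) == 1) per_traj <- matrix(per_traj, nrow = 1)
  states <- sort(unique(as.vector(per_traj)))
  out <- matrix(0, length(t_grid), length(states),
                dimnames = list(NULL, states))
  for (j in seq_along(states))
    out[, j] <- rowMeans(per_traj == states[j])
  attr(out, "t") <- t_grid
  out
}

#' Detect population equilibrium
#'
#' The earliest grid time from which every state's population stays within
#' `tolerance` of its final value through the end of the series, provided
#' the settled stretch is at least `window` long; NA if the series never
#' settles for that long (as for the indefinitely fluctuating triplet Sz
#' sublevel populations).
#'
#' @param series population matrix from [population_time_series()]
#' @param window minimum settled duration, in the time units of the grid
#' @param tolerance allowed deviation from the final value (fraction)
#' @return time in fs, or NA
#' @export
detect_equilibrium <- function(series, window, tolerance = 0.01) {
  t_grid <- attr(series, "t")
  if (is.null(t_grid)) t_grid <- seq_len(nrow(series))
  span <- t_grid[length(t_grid)] - t_grid[1]
  if (window > span)
    stop("window (", window, ") longer than the series span (", span, ")",
         call. = FALSE)
  final <- series[nrow(series), ]
  dev <- sweep(series, 2, final)
  ok <- apply(abs(dev) <= tolerance, 1, all)
  bad <- which(!ok)   # the last bad row blocks all earlier times
  t_eq <- if (length(bad) == 0) t_grid[1] else {
    if (max(bad) == nrow(series)) return(NA_real_)
    t_grid[max(bad) + 1]
  }
  if (t_grid[length(t_grid)] - t_eq < window) return(NA_real_)
  t_eq
}

#' Two-dimensional histogram
#'
#' Standard 2-D binning on the given edges; bins are right-open except the
#' last, which is closed, so a point on a shared interior edge is assigned
#' to the higher bin and points on the upper boundary are kept.
#'
#' @param x,y equal-length numeric vectors
#' @param x_edges,y_edges strictly increasing bin edges
#' @return integer matrix of counts, (length(x_edges)-1) rows by
#'   (length(y_edges)-1) columns
#' @export
histogram2d <- function(x, y, x_edges, y_edges) {
  stopifnot(length(x) == length(y))
  if (is.unsorted(x_edges, strictly = TRUE) ||
      is.unsorted(y_edges, strictly = TRUE))
    stop("bin edges must be strictly increasing", call. = FALSE)
  bin <- function(v, edges) {
    i <- findInterval(v, edges, left.open = FALSE, rightmost.closed = TRUE)
    i[v < edges[1] | v > edges[length(edges)]] <- NA
    i
  }
  bx <- bin(x, x_edges); by <- bin(y, y_edges)
  nx <- length(x_edges) - 1; ny <- length(y_edges) - 1
  counts <- matrix(0L, nx, ny)
  ok <- !is.na(bx) & !is.na(by)
  for (i in which(ok))
    counts[bx[i], by[i]] <- counts[bx[i], by[i]] + 1L
  counts
}

#' Endpoint-subrange (RLSE) feature report
#'
#' For an initial-velocity feature, computes the global range over all
#' trajectories, the per-product-state subranges, and for each state and
#' each endpoint the empty-subrange length (distance from the global
#' endpoint to the state's nearest extreme on that side) as a percentage of
#' the global range length: the relative length of the subrange near an
#' end point (RLSE). A state whose values reach an endpoint has RLSE 0
#' there; a large RLSE means trajectories with feature values near that
#' endpoint never produce this state, making the feature a strong
#' classifier for it.
#'
#' @param feature_values numeric feature vector, one per trajectory
#' @param product_labels product-state label per trajectory
#' @return a list of class `dioxhop_rlse` with `feature_range`, and
#'   per-state `subrange`, `rlse_lower`, `rlse_upper` (percent)
#' @export
rlse_report <- function(feature_values, product_labels) {
  stopifnot(length(feature_values) == length(product_labels))
  lo <- min(feature_values); hi <- max(feature_values)
  len <- hi - lo
  if (len <= 0)
    stop("undefined error: zero feature range length", call. = FALSE)
  states <- sort(unique(product_labels))
  per_state <- lapply(states, function(s) {
    v <- feature_values[product_labels == s]
    sub <- c(min(v), max(v))
    list(subrange = sub,
         rlse_lower = 100 * (sub[1] - lo) / len,
         rlse_upper = 100 * (hi - sub[2]) / len)
  })
  names(per_state) <- states
  structure(list(feature_range = c(lo, hi), states = per_state),
            class = "dioxhop_rlse")
}

#' RLSE from printed subrange bounds
#'
#' Pure interval arithmetic: given the global range and a state's
#' subrange, the RLSE at each endpoint is the empty length between the
#' global endpoint and the subrange, as a percentage of the global range
#' length.
#'
#' @param global_range numeric length-2 (lo, hi)
#' @param subrange numeric length-2 (lo, hi), contained in `global_range`
#' @return named vector with `lower` and `upper` RLSE percentages
#' @export
rlse_from_ranges <- function(global_range, subrange) {
  len <- diff(global_range)
  if (len <= 0) stop("undefined error: zero range length", call. = FALSE)
  c(lower = 100 * (subrange[1] - global_range[1]) / len,
    upper = 100 * (global_range[2] - subrange[2]) / len)
}

#' Table of dissociation-time statistics by product state
#'
#' Minimum, maximum, half-time (median), mean and standard deviation of
#' the dissociation times, per product state and over all dissociated
#' trajectories.
#'
#' @param result a `dioxhop_ensemble_result`
#' @return data.frame with one row per product state plus "all"
#' @export
dissociation_table <- function(result) {
  td <- vapply(result$summaries, function(s) s$dissociation_time %||% NA_real_,
               numeric(1))
  lab <- vapply(result$summaries, function(s) s$product %||% NA_character_,
                character(1))
  ok <- is.finite(td)
  td <- td[ok]; lab <- lab[ok]
  groups <- c(as.list(split(td, lab)), list(all = td))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(state = g, n = length(v), min = min(v), max = max(v),
               half_time = stats::median(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
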