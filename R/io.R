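#' Default run configuration
#'
#' The complete configuration of a simulation-and-analysis run: model
#' parameters, engine parameters (0.5 fs step, 2.4/3.7 angstrom
#' dissociation/termination distances), sampling parameters (300 K,
#' 3.96 eV launch kinetic energy), analysis parameters (peak prominence,
#' histogram bin widths), trajectory count, master seed and output
#' directory. Configurations round-trip losslessly through YAML and
#' unknown keys are rejected with the offending key named.
#'
#' @return nested named list
#' @export
default_run_config <- function() {
  list(
    model = default_model_config(),
    engine = list(dt = 0.5, electronic_substeps = 25, t_max = 2000,
                  r_dissoc = 2.4, r_terminate = 3.7,
                  decoherence_constant = 2.72,
                  energy_drift_tolerance = 0.2, fd_step = 1e-4,
                  frustrated_reversal = FALSE),
    sampling = list(temperature = 300, target_ke = 3.96, method = "flip"),
    analysis = list(r_dissoc = 2.4, min_prominence = 0.05,
                    time_bin = 100, angle_bin = 10, omega_bin = 0.5,
                    equilibrium_tolerance = 0.01),
    n_trajectories = 310L,
    master_seed = 1L,
    out_dir = "results"
  )
}

#' Read a run configuration file
#'
#' Parses a YAML configuration, merges it over the defaults and rejects
#' unknown keys (naming the first offending key).
#'
#' @param path YAML file path
#' @return full configuration list
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merge_config(default_run_config(), cfg)
}

#' Write a run configuration file
#'
#' @param config configuration list (validated against the defaults)
#' @param path output YAML path
#' @export
write_run_config <- function(config, path) {
  config <- merge_config(default_run_config(), config)
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' Print the full default configuration
#'
#' The equivalent of a `config --dump-defaults` command: emits the complete
#' default configuration as YAML text.
#'
#' @param file connection or "" for stdout
#' @export
dump_default_config <- function(file = "") {
  cat(yaml::as.yaml(default_run_config(), precision = 15), file = file)
  invisible(NULL)
}

#' Engine parameters from a run configuration
#'
#' @param config a run configuration list
#' @return a `dioxhop_params`
#' @export
engine_params_from_config <- function(config) {
  e <- config$engine; s <- config$sampling
  engine_params(dt = e$dt, electronic_substeps = e$electronic_substeps,
                t_max = e$t_max, r_dissoc = e$r_dissoc,
                r_terminate = e$r_terminate,
                decoherence_constant = e$decoherence_constant,
                energy_drift_tolerance = e$energy_drift_tolerance,
                fd_step = e$fd_step, temperature = s$temperature,
                target_ke = s$target_ke,
                frustrated_reversal = e$frustrated_reversal)
}

#' Write a trajectory to delimited text
#'
#' Writes the step table as a tab-delimited file (`<path>.steps.tsv`,
#' header line naming the columns; angles in degrees, energies in eV) and
#' the sidecar summary (`<path>.summary.yaml`: status, product label,
#' dissociation time, hop list). Numeric values are written with 17
#' significant digits so the round trip is exact.
#'
#' @param record a `dioxhop_trajectory`
#' @param path file stem (without extension)
#' @return invisibly, the two file paths
#' @export
write_trajectory <- function(record, path) {
  if (nrow(record$steps) < 1)
    stop("cannot write a trajectory with no steps", call. = FALSE)
  steps_path <- paste0(path, ".steps.tsv")
  sum_path <- paste0(path, ".summary.yaml")
  df <- record$steps
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, steps_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hops <- record$hops
  hop_list <- if (nrow(hops) > 0) lapply(seq_len(nrow(hops)), function(i)
    as.list(hops[i, ])) else list()
  yaml::write_yaml(list(
    status = record$status,
    product_mch = record$product_mch,
    product_collapsed = record$product_collapsed,
    dissociation_time = record$dissociation_time,
    label_drift = record$label_drift,
    dt = record$dt,
    hops = hop_list
  ), sum_path, precision = 15)
  invisible(c(steps_path, sum_path))
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Columns are matched by name from the header, so column order is free.
#' Missing required columns raise a parse error naming them.
#'
#' @param path file stem used at write time
#' @return a `dioxhop_trajectory`
#' @export
read_trajectory <- function(path) {
  steps_path <- paste0(path, ".steps.tsv")
  sum_path <- paste0(path, ".summary.yaml")
  if (!file.exists(steps_path))
    stop("parse error: no step table at ", steps_path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(steps_path, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", steps_path, ": ",
                             conditionMessage(e), call. = FALSE))
  required <- c("t", "r_cc", "phi_oocc", "phi_cccc", "active_diag",
                "active_mch", "e_active", "e_total")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("parse error: missing column(s) ", paste(missing, collapse = ", "),
         " (header line 1)", call. = FALSE)
  bad <- which(!vapply(df$t, function(x) is.finite(suppressWarnings(
    as.numeric(x))), logical(1)))
  if (length(bad) > 0)
    stop("parse error: malformed row at line ", bad[1] + 1, call. = FALSE)
  extra <- setdiff(names(df), required)
  df <- df[, c(required, extra)]
  meta <- if (file.exists(sum_path)) yaml::read_yaml(sum_path) else list()
  hops <- if (length(meta$hops) > 0) do.call(rbind, lapply(meta$hops,
                                                           as.data.frame))
          else data.frame(t = numeric(0), from_diag = integer(0),
                          to_diag = integer(0), from_mch = character(0),
                          to_mch = character(0), frustrated = logical(0),
                          velocity_fallback = logical(0))
  structure(list(
    steps = df, hops = hops,
    status = meta$status %||% NA_character_,
    product_mch = meta$product_mch %||% NA_character_,
    product_collapsed = meta$product_collapsed %||% NA_character_,
    dissociation_time = meta$dissociation_time %||% NA_real_,
    label_drift = meta$label_drift %||% NA,
    dt = meta$dt %||% (if (nrow(df) > 1) df$t[2] - df$t[1] else NA_real_),
    initial = NULL
  ), class = "dioxhop_trajectory")
}

#' Load a packaged worked-example fixture
#'
#' The package ships the printed worked-example data of the study it
#' implements as plain-text fixtures: the two 10-state transition-count
#' matrices (a short and a long representative trajectory ending in T1),
#' the product-state trajectory counts over the 302 completed
#' trajectories, the dihedral waypoint sequence of the long trajectory,
#' and the feature ranges behind the endpoint-subrange (RLSE)
#' percentages.
#'
#' @param name one of "table2_matrix", "table3_matrix", "table4_counts",
#'   "dihedral_waypoints_traj23", "rlse_ranges_fig5"
#' @return a typed object: a `dioxhop_tcm` for the matrices, a named count
#'   vector with an `n_completed` attribute for the counts, a numeric
#'   vector for the waypoints, a nested list for the RLSE ranges
#' @export
load_fixture <- function(name) {
  dir <- system.file("extdata", package = "dioxhop")
  path <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("fixture file missing: ", f, call. = FALSE)
    p
  }
  switch(name,
    table2_matrix = read_tcm_fixture(path("transition_counts_short_t1.tsv")),
    table3_matrix = read_tcm_fixture(path("transition_counts_long_t1.tsv")),
    table4_counts = {
      x <- jsonlite::read_json(path("product_state_counts.json"),
                               simplifyVector = TRUE)
      counts <- unlist(x$counts)
      attr(counts, "n_completed") <- x$n_completed
      counts
    },
    dihedral_waypoints_traj23 = as.numeric(utils::read.table(
      path("dihedral_waypoints_long_t1.txt"))$V1),
    rlse_ranges_fig5 = jsonlite::read_json(path("rlse_feature_ranges.json"),
                                           simplifyVector = TRUE),
    stop("lookup error: unknown fixture '", name, "'", call. = FALSE)
  )
}

read_tcm_fixture <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                          comment.char = "#")
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  stopifnot(nrow(m) == ncol(m), all(rownames(m) == colnames(m)))
  structure(list(labels = colnames(m), counts = m, dt = 0.5),
            class = "dioxhop_tcm")
}

#' Read a standalone MCH-series file
#'
#' One state label per line (the vocabulary of [spin_state_labels()]),
#' e.g. for checking transition-count matrices from externally supplied
#' state series.
#'
#' @param path text file path
#' @return character vector of labels
#' @export
read_mch_series <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
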