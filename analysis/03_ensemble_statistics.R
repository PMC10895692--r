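#!/usr/bin/env Rscript
# Stage 3: ensemble statistics.
#
# From the stored trajectories: chemiexcitation quantum yields per product
# state, the dissociation-time table (min/max/half-time/mean/sd per
# product state), ensemble-averaged population time series in the
# collapsed-MCH, full-MCH and diagonal bases with equilibrium detection,
# 2-D histograms of trajectory counts over (dissociation time, dissociation
# dihedral angle) and over (dissociation time, initial dihedral angular
# velocity), and the endpoint-subrange (RLSE) reports for the
# initial-velocity features. Optional figures mirror the distribution and
# population panels when ggplot2 is available.

suppressMessages(library(dioxhop))

out_dir <- "results"
traj_dir <- file.path(out_dir, "trajectories")
stems <- sub("\\.steps\\.tsv$", "",
             list.files(traj_dir, pattern = "\\.steps\\.tsv$",
                        full.names = TRUE))
records <- lapply(stems, read_trajectory)
completed <- records[vapply(records, function(x)
  x$status != "failed_energy", logical(1))]
message(length(records), " launched, ", length(completed), " completed, ",
        length(records) - length(completed), " failed")

res <- ensemble_result(records)
diss_tab <- dissociation_table(res)
write.table(diss_tab, file.path(out_dir, "dissociation_times.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(diss_tab)

labs <- vapply(res$summaries, function(s) s$product, character(1))
labs <- labs[!is.na(labs)]
yields <- quantum_yields(labs, length(labs))
message("quantum yields (%): ",
        paste(names(yields), round(yields, 1), collapse = ", "))

# population time series and equilibrium detection
t_grid <- seq(0, 2000, by = 5)
pops <- list()
for (basis in c("mch_collapsed", "mch_full", "diagonal")) {
  pop <- population_time_series(completed, basis, t_grid)
  df <- data.frame(t = t_grid, pop, check.names = FALSE)
  write.table(df, file.path(out_dir, paste0("populations_", basis, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pops[[basis]] <- pop
  eq <- detect_equilibrium(pop, window = 200, tolerance = 0.02)
  message(basis, " populations reach equilibrium at: ",
          if (is.na(eq)) "never (within tolerance)" else paste(eq, "fs"))
}

# 2-D histograms: dissociation time x dissociation dihedral angle
# (res$summaries is index-aligned with `completed`)
td <- vapply(res$summaries, function(s) s$dissociation_time, numeric(1))
ok <- is.finite(td)
# dissociation dihedral = wrapped phi at the first crossing of 2.4 A
phi_d <- vapply(which(ok), function(i) {
  s <- completed[[i]]$steps
  s$phi_oocc[which(s$r_cc > 2.4)[1]]
}, numeric(1))
h <- histogram2d(td[ok], phi_d, seq(0, 2100, 100), seq(-180, 180, 10))
write.table(h, file.path(out_dir, "hist_time_x_dissociation_angle.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

# RLSE reports for the initial-velocity features
feat_names <- c("omega0_1234", "omega0_3456", "v0_34", "v0_12", "v0_56")
rlse_all <- list()
for (fn in feat_names) {
  vals <- vapply(res$summaries, function(s)
    if (is.null(s$features)) NA_real_ else s$features[[fn]], numeric(1))
  sel <- ok & is.finite(vals)
  if (sum(sel) < 3 || length(unique(labs)) < 2) next
  rep <- rlse_report(vals[sel], vapply(res$summaries[sel], function(s)
    s$product, character(1)))
  rlse_all[[fn]] <- list(
    range = rep$feature_range,
    states = lapply(rep$states, function(s)
      list(subrange = s$subrange, rlse_lower = round(s$rlse_lower, 1),
           rlse_upper = round(s$rlse_upper, 1))))
  for (st in names(rep$states))
    message(sprintf("RLSE %s / %s: lower %.1f%%, upper %.1f%%", fn, st,
                    rep$states[[st]]$rlse_lower,
                    rep$states[[st]]$rlse_upper))
}
jsonlite::write_json(rlse_all, file.path(out_dir, "rlse_report.json"),
                     auto_unbox = TRUE, digits = 6)
jsonlite::write_json(
  list(n_launched = res$n_launched, n_completed = res$n_completed,
       n_failed = res$n_failed,
       yields_percent = as.list(round(yields, 1)),
       half_times_fs = setNames(as.list(diss_tab$half_time),
                                diss_tab$state)),
  file.path(out_dir, "ensemble_report.json"), auto_unbox = TRUE,
  digits = 6)

# optional figures
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  dfh <- data.frame(td = td[ok], phi = phi_d,
                    product = vapply(res$summaries[ok], function(s)
                      s$product, character(1)))
  p1 <- ggplot(dfh, aes(td, phi)) +
    geom_bin2d(binwidth = c(100, 10)) +
    facet_wrap(~product) +
    labs(x = "dissociation time (fs)",
         y = "dissociation dihedral angle (deg)")
  ggsave(file.path(fig_dir, "dissociation_distribution.pdf"), p1,
         width = 9, height = 3.2)
  pop <- pops$mch_collapsed
  dfp <- data.frame(t = rep(t_grid, ncol(pop)),
                    state = rep(colnames(pop), each = nrow(pop)),
                    population = as.vector(pop))
  p2 <- ggplot(dfp, aes(t, population, colour = state)) +
    geom_line() +
    labs(x = "time (fs)", y = "MCH population fraction")
  ggsave(file.path(fig_dir, "populations_mch.pdf"), p2,
         width = 7, height = 4)
  message("figures written to ", fig_dir)
}
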