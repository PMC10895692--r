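test_that("dissociation time is the first strict crossing", {
  rec <- list(steps = data.frame(t = c(0, 0.5, 1.0, 1.5),
                                 r_cc = c(2.0, 2.3, 2.45, 3.0)))
  expect_equal(dissociation_time(rec), 1.0)
  rec2 <- list(steps = data.frame(t = c(0, 0.5, 1.0),
                                  r_cc = c(2.0, 2.39, 2.4)))  # never > 2.4
  expect_true(is.na(dissociation_time(rec2)))
})

test_that("product labels collapse Sz sublevels and stay frozen", {
  rec <- list(steps = data.frame(
    t = seq(0, 1.5, 0.5), r_cc = c(2.0, 2.5, 3.0, 3.8),
    active_mch = c("S1", "T1,-1", "T1,0", "T1,1")))
  expect_equal(product_state_label(rec), "T1")
  rec2 <- list(steps = data.frame(t = c(0, 0.5), r_cc = c(2.0, 2.6),
                                  active_mch = c("S0", "S0")))
  expect_equal(product_state_label(rec2), "S0")
  rec3 <- list(steps = data.frame(t = 0, r_cc = 2.0, active_mch = "S0"))
  expect_error(product_state_label(rec3), "undefined-product")
  # consistency with the engine's frozen product label on real records
  ens <- shared_small_ensemble()
  for (tr in ens) {
    if (tr$status != "dissociated") next
    expect_equal(product_state_label(tr), tr$product_collapsed)
  }
})

test_that("frustrated dissociations equal the peaks of the C-C series", {
  # a ~40 fs oscillation sampled at 0.5 fs over 975.5 fs, starting at a
  # turning point: 24 interior maxima, one per completed oscillation
  t <- seq(0, 975.5, by = 0.5)
  r <- 1.6 + 0.2 * cos(2 * pi * t / 40)
  expect_equal(count_frustrated_dissociations(r), 24)
  expect_equal(mean_oscillation_period(24, 975.5), 975.5 / 24)
  expect_equal(round(mean_oscillation_period(24, 975.5), 1), 40.6)
  # monotone series has no peaks
  expect_equal(count_frustrated_dissociations(seq(1.5, 3.5, 0.01)), 0)
  # prominence filter suppresses sub-threshold jitter
  rj <- r + 0.01 * sin(2 * pi * t / 3)
  expect_equal(count_frustrated_dissociations(rj, min_prominence = 0.05), 24)
  # counting window excludes peaks after the end index
  r2 <- c(r, 1.6 + 0.2 * cos(2 * pi * seq(976, 1100, 0.5) / 40))
  expect_equal(count_frustrated_dissociations(r2, end_index = length(r)), 24)
})

test_that("peak counting matches a brute-force oracle on random walks", {
  set.seed(77)
  for (i in 1:100) {
    r <- 1.6 + cumsum(rnorm(200, 0, 0.05))
    for (prom in c(0, 0.02, 0.05, 0.2)) {
      expect_equal(count_frustrated_dissociations(r, prom),
                   brute_force_peak_count(r, prom),
                   info = paste("series", i, "prom", prom))
    }
  }
})

test_that("mean oscillation periods reproduce the worked values", {
  expect_equal(round(mean_oscillation_period(108, 4300.0), 1), 39.8)
  expect_equal(mean_oscillation_period(1, 40.0), 40.0)
  expect_true(is.na(mean_oscillation_period(0, 100)))
})

test_that("transition-count matrices tabulate steps and hops", {
  tcm <- transition_count_matrix(c("S0", "S0", "S0"))
  expect_equal(tcm$counts["S0", "S0"], 2L)
  expect_equal(sum(tcm$counts), 2L)
  tcm2 <- transition_count_matrix(c("S0", "T1,-1", "T1,-1"))
  expect_equal(tcm2$counts["S0", "T1,-1"], 1L)
  expect_equal(tcm2$counts["T1,-1", "T1,-1"], 1L)
  expect_equal(sum(tcm2$counts), 2L)
  expect_error(transition_count_matrix(c("S0", "X9"), labels = c("S0")),
               "unknown state label")
  # counting identity on random series
  set.seed(11)
  vocab <- spin_state_labels(4, 4)$name
  for (i in 1:50) {
    s <- sample(vocab, sample(2:60, 1), replace = TRUE)
    tcm <- transition_count_matrix(s)
    expect_equal(sum(tcm$counts), length(s) - 1L)
  }
})

test_that("residence rule: diagonal plus off-diagonal column sum", {
  t2 <- load_fixture("table2_matrix")
  res2 <- residence_times(t2)
  expect_equal(unname(res2$collapsed[c("S0", "S1", "T1", "T2")]),
               c(30.5, 5.5, 34.0, 9.5))
  expect_equal(res2$total, 79.5)
  t3 <- load_fixture("table3_matrix")
  res3 <- residence_times(t3)
  expect_equal(unname(res3$collapsed[c("S0", "S1", "S2", "S3", "T1", "T2")]),
               c(30.5, 113.5, 24.5, 12.5, 546.0, 317.0))
  # conservation identity
  expect_equal(res3$total, sum(t3$counts) * t3$dt)
})

test_that("residence times equal a destination-convention direct count", {
  set.seed(19)
  vocab <- spin_state_labels(2, 2)$name
  for (i in 1:50) {
    s <- sample(vocab, sample(5:80, 1), replace = TRUE)
    tcm <- transition_count_matrix(s, labels = vocab, dt = 0.5)
    res <- residence_times(tcm)
    # destination convention: sample j (j >= 2) is attributed to its state
    direct <- table(factor(s[-1], levels = vocab)) * 0.5
    expect_equal(unname(res$per_state), as.numeric(direct))
    expect_equal(res$total, (length(s) - 1) * 0.5)
  }
})

test_that("dihedral unwrapping is continuous and translation-invariant", {
  # oscillation across the 180/-180 seam
  expect_equal(unwrap_dihedral(c(178, -177)), c(178, 183))
  expect_equal(unwrap_dihedral(c(10, 10, 10)), c(10, 10, 10))
  # roundtrip: wrapped random walk recovers the original path shape
  set.seed(23)
  for (i in 1:50) {
    path <- cumsum(c(runif(1, -180, 180), rnorm(100, 0, 40)))
    wrapped <- wrap_angle(path)
    un <- unwrap_dihedral(wrapped)
    expect_equal(diff(un), diff(path), tolerance = 1e-9)
    k <- (un - path) / 360
    expect_equal(k, round(k), tolerance = 1e-9)
    # adding 360 to all inputs changes nothing but the branch
    un2 <- unwrap_dihedral(wrap_angle(path + 360))
    expect_equal(diff(un2), diff(un), tolerance = 1e-9)
  }
})

test_that("angle variation reproduces the worked waypoint values", {
  expect_equal(angle_variation(c(135.8, 180, -90, 0, 32.9)), 257.1,
               tolerance = 1e-9)
  # the same waypoints entered through the -180 representative
  expect_equal(angle_variation(c(135.8, -180, -90, 0, 32.9)), 257.1,
               tolerance = 1e-9)
  expect_equal(angle_variation(c(135.8, 128.9)), 6.9, tolerance = 1e-9)
  expect_equal(angle_variation(c(135.8, 150.0)), 14.2, tolerance = 1e-9)
})

test_that("per-trajectory summaries assemble the per-record statistics", {
  ens <- shared_small_ensemble()
  tr <- ens[[which(vapply(ens, function(x) x$status == "dissociated",
                          logical(1)))[1]]]
  s <- summarize_trajectory(tr)
  expect_equal(s$dissociation_time, tr$dissociation_time)
  expect_equal(s$product, tr$product_collapsed)
  expect_gte(s$n_frustrated, 0)
  expect_equal(sum(s$residence), (nrow(tr$steps) - 1) * tr$dt)
  expect_true(is.finite(s$angle_variation))
})
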