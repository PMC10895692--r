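KE_CONV <- dioxhop_constants$ke
HBAR <- dioxhop_constants$hbar

test_that("velocity-Verlet reproduces the harmonic period within 0.5%", {
  mass <- 22; k <- 56.25   # eV/A^2 -> period 2*pi*sqrt(m*conv/k)
  grad <- function(q) k * q
  dt <- 0.5
  q <- 0.3; v <- 0
  qs <- numeric(4000)
  g <- NULL
  for (i in seq_len(4000)) {
    st <- propagate_nuclei(q, v, grad, dt, mass, g)
    q <- st$q; v <- st$v; g <- st$g
    qs[i] <- q
  }
  # period from mean spacing of rising zero crossings
  cross <- which(qs[-1] > 0 & qs[-length(qs)] <= 0)
  period <- mean(diff(cross)) * dt
  exact <- 2 * pi * sqrt(mass * KE_CONV / k)
  expect_lt(abs(period - exact) / exact, 0.005)
})

test_that("zero force gives uniform linear motion", {
  st <- propagate_nuclei(c(1, 2), c(0.1, -0.2), function(q) c(0, 0),
                         0.5, c(1, 1))
  expect_equal(st$q, c(1.05, 1.9))
  expect_equal(st$v, c(0.1, -0.2))
})

test_that("halving the step quarters the total-energy drift on a Morse well", {
  mass <- 22; De <- 1.0; a <- 5.3; re <- 1.6
  pot <- function(r) De * (1 - exp(-a * (r - re)))^2
  grad <- function(r) 2 * De * a * exp(-a * (r - re)) * (1 - exp(-a * (r - re)))
  run <- function(dt, nstep) {
    q <- 1.75; v <- 0
    e0 <- pot(q)
    drift <- 0
    g <- NULL
    for (i in seq_len(nstep)) {
      st <- propagate_nuclei(q, v, grad, dt, mass, g)
      q <- st$q; v <- st$v; g <- st$g
      e <- pot(q) + 0.5 * mass * v^2 * KE_CONV
      drift <- max(drift, abs(e - e0))
    }
    drift
  }
  d1 <- run(0.5, 400)
  d2 <- run(0.25, 800)
  expect_gt(d1 / d2, 2.8)   # second-order integrator: ratio ~ 4
  expect_lt(d1 / d2, 5.5)
  expect_error(propagate_nuclei(1, 0, function(q) NaN, 0.5, 1),
               "non-finite gradient")
})

test_that("decoupled electronic states only accumulate phase", {
  E <- c(0.2, -0.1, 0.5)
  h <- diag(E)
  c0 <- c(0.6, 0.64, sqrt(1 - 0.6^2 - 0.64^2)) + 0i
  dt <- 2.0
  c1 <- propagate_electronic(c0, h, h, dt, 10)
  expect_equal(Mod(c1), Mod(c0), tolerance = 1e-12)
  expect_equal(c1, c0 * exp(-1i * E * dt / HBAR), tolerance = 1e-10)
})

test_that("two-state Rabi transfer matches the closed form within 1e-6", {
  V <- 0.05
  h <- matrix(c(0, V, V, 0), 2)
  c0 <- c(1, 0) + 0i
  t_tot <- 10
  # exact path (constant Hamiltonian)
  c1 <- propagate_electronic(c0, h, h, t_tot, 1)
  expect_equal(Mod(c1[2])^2, sin(V * t_tot / HBAR)^2, tolerance = 1e-10)
  # sub-stepped Strang path (diagonal changes negligibly across the step)
  h2 <- h; diag(h2) <- c(1e-12, 0)
  c2 <- c0
  for (i in 1:20) c2 <- propagate_electronic(c2, h, h2, t_tot / 20, 50)
  expect_equal(Mod(c2[2])^2, sin(V * t_tot / HBAR)^2, tolerance = 1e-6)
  # general path (changing off-diagonal): still unitary and accurate for
  # a slowly varying Hamiltonian
  h3 <- matrix(c(0, 1.0001 * V, 1.0001 * V, 0), 2)
  c3 <- propagate_electronic(c0, h, h3, t_tot, 400)
  expect_equal(sum(Mod(c3)^2), 1, tolerance = 1e-10)
  expect_equal(Mod(c3[2])^2, sin(1.00005 * V * t_tot / HBAR)^2,
               tolerance = 1e-5)
})

test_that("electronic propagation is unitary over long runs", {
  set.seed(8)
  K <- 4
  A <- matrix(complex(real = rnorm(K * K), imaginary = rnorm(K * K)), K)
  h0 <- (A + Conj(t(A))) / 2 * 0.1
  c0 <- rep(1 / sqrt(K), K) + 0i
  cc <- c0
  for (i in 1:10) {
    h1 <- h0; diag(h1) <- diag(h1) + rnorm(K, 0, 0.01)
    cc <- propagate_electronic(cc, h0, h1, 0.5, 25)
    h0 <- h1
  }
  expect_equal(sum(Mod(cc)^2), 1, tolerance = 1e-10)
})

test_that("hop probabilities follow the fewest-switches prescription", {
  c0 <- c(sqrt(0.7), sqrt(0.3)) + 0i
  h_diag <- diag(c(0, 0.2))
  expect_equal(hop_probabilities(c0, h_diag, 1, 0.5), c(0, 0))
  # masked target has zero probability regardless of flux
  V <- 0.05
  h <- matrix(c(0, 1i * V, -1i * V, 0.1), 2)
  c1 <- propagate_electronic(c(1, 0) + 0i, h, h, 0.5, 25)
  g <- hop_probabilities(c1, h, 1, 0.5)
  expect_gt(g[2], 0)
  gm <- hop_probabilities(c1, h, 1, 0.5, mask = 2)
  expect_equal(gm[2], 0)
  expect_error(hop_probabilities(c(0, 1) + 0i, h, 1, 0.5),
               "degenerate-state")
})

test_that("hop statistics track the exact two-state quantum transfer", {
  # Degenerate two-level system with constant coupling: while the flux is
  # one-way, the expected fraction of hopped trajectories equals the exact
  # quantum population of the target state.
  V <- 0.02
  h <- matrix(c(0, V, V, 0), 2)
  dt <- 0.25
  nstep <- 40   # stays inside the first quarter Rabi period
  M <- 4000
  cc <- c(1, 0) + 0i
  set.seed(31)
  active <- rep(1L, M)
  for (s in seq_len(nstep)) {
    cc <- propagate_electronic(cc, h, h, dt, 5)
    g1 <- hop_probabilities(cc, h, 1, dt)
    g2 <- hop_probabilities(cc, h, 2, dt)
    z <- runif(M)
    on1 <- active == 1L
    active[on1 & z < g1[2]] <- 2L
    active[!on1 & z < g2[1]] <- 1L
  }
  p2_exact <- sin(V * nstep * dt / HBAR)^2
  p2_mc <- mean(active == 2L)
  se <- sqrt(p2_exact * (1 - p2_exact) / M)
  expect_lt(abs(p2_mc - p2_exact), 4 * se + 0.01)
})

test_that("hops conserve energy exactly or are frustrated", {
  masses <- c(22, 1, 1)
  v <- c(0.04, 0.1, -0.05)
  dir <- c(1, 0, 0)
  ke0 <- 0.5 * sum(masses * v^2) * KE_CONV
  # downhill hop: energy moved into the directed component
  res <- attempt_hop(v, dir, masses, de = -0.5)
  expect_true(res$accepted)
  ke1 <- 0.5 * sum(masses * res$v^2) * KE_CONV
  expect_equal(ke1 - ke0, 0.5, tolerance = 1e-9)
  expect_equal(res$v[-1], v[-1])
  # uphill with insufficient directed kinetic energy: frustrated
  ke_dir <- 0.5 * masses[1] * v[1]^2 * KE_CONV
  res2 <- attempt_hop(v, dir, masses, de = ke_dir + 0.1)
  expect_false(res2$accepted)
  expect_equal(res2$v, v)
  # zero gap: velocities unchanged
  res3 <- attempt_hop(v, dir, masses, de = 0)
  expect_true(res3$accepted)
  expect_equal(res3$v, v, tolerance = 1e-12)
  # zero coupling direction falls back to the full velocity vector
  res4 <- attempt_hop(v, c(0, 0, 0), masses, de = -0.2)
  expect_true(res4$fallback)
  expect_true(res4$accepted)
  ke4 <- 0.5 * sum(masses * res4$v^2) * KE_CONV
  expect_equal(ke4 - ke0, 0.2, tolerance = 1e-9)
})

test_that("energy-based decoherence damps as the closed form prescribes", {
  c0 <- c(sqrt(0.8), sqrt(0.2)) + 0i
  E <- c(0, 0.3)
  # all population on the active state: unchanged
  expect_equal(apply_decoherence(c(1, 0) + 0i, E, 1, 1.5, 0.5), c(1, 0) + 0i)
  # scalar oracle for the damped magnitude
  ekin <- 1.5; dt <- 0.5; C <- 2.72
  tau <- HBAR / abs(E[2] - E[1]) * (1 + C / ekin)
  out <- apply_decoherence(c0, E, 1, ekin, dt, C)
  expect_equal(Mod(out[2]), sqrt(0.2) * exp(-dt / tau), tolerance = 1e-12)
  expect_equal(sum(Mod(out)^2), 1, tolerance = 1e-12)
  # huge time: full collapse onto the active state
  out2 <- apply_decoherence(c0, E, 1, ekin, 1e6, C)
  expect_equal(Mod(out2), c(1, 0), tolerance = 1e-10)
  # degenerate state: no damping
  out3 <- apply_decoherence(c0, c(0, 0), 1, ekin, 0.5, C)
  expect_equal(out3, c0)
})

test_that("trajectories are deterministic given the master seed", {
  m <- small_model()
  p <- small_params(t_max = 40)
  e1 <- run_ensemble(m, 2, p, master_seed = 5)
  e2 <- run_ensemble(m, 2, p, master_seed = 5)
  expect_identical(e1[[1]]$steps, e2[[1]]$steps)
  expect_identical(e1[[2]]$steps, e2[[2]]$steps)
  expect_identical(e1[[1]]$hops, e2[[1]]$hops)
  e3 <- run_ensemble(m, 1, p, master_seed = 6)
  expect_length(e3, 1)
  expect_false(identical(e1[[1]]$steps, e3[[1]]$steps))
})

test_that("a trajectory record satisfies its structural invariants", {
  ens <- shared_small_ensemble()
  tr <- ens[[which.max(vapply(ens, function(x) nrow(x$steps), numeric(1)))]]
  s <- tr$steps
  expect_equal(diff(s$t), rep(tr$dt, nrow(s) - 1))
  # energy conservation within the drift tolerance while running
  expect_lt(max(abs(s$e_total - s$e_total[1])), 0.2)
  # active MCH label changes only at hop times or reassignment rows;
  # every recorded hop time exists in the step grid
  if (nrow(tr$hops) > 0)
    expect_true(all(tr$hops$t %in% s$t))
  if (tr$status == "dissociated") {
    expect_gt(s$r_cc[nrow(s)], 3.7)
    expect_false(is.na(tr$dissociation_time))
    i <- which(s$r_cc > 2.4)[1]
    expect_equal(tr$dissociation_time, s$t[i])
    expect_equal(tr$product_mch, s$active_mch[i])
  }
})

test_that("the ensemble stays in the physical regime", {
  ens <- shared_small_ensemble()
  st <- vapply(ens, function(x) x$status, character(1))
  # failed-energy fraction at most 5%
  expect_lte(sum(st == "failed_energy") / length(ens), 0.05)
  # products restricted to the allowed manifold; collapsed labels frozen
  pr <- vapply(ens, function(x) x$product_collapsed, character(1))
  expect_true(all(is.na(pr) | pr %in% c("S0", "S1", "T1", "T2")))
  expect_false(any(vapply(ens, function(x) isTRUE(x$label_drift),
                          logical(1))))
  # a healthy fraction dissociates, with times beyond the sanity bound
  td <- vapply(ens, function(x) x$dissociation_time, numeric(1))
  expect_gt(sum(is.finite(td)), length(ens) / 3)
  expect_gte(min(td, na.rm = TRUE), 10)
})

test_that("without SOC the dynamics conserve spin", {
  m0 <- small_model(soc_st = 0, soc_tt = 0)
  ens <- run_ensemble(m0, 6, small_params(t_max = 150), master_seed = 13)
  for (tr in ens) {
    expect_true(all(substr(tr$steps$active_mch, 1, 1) == "S"))
    if (!is.na(tr$product_collapsed))
      expect_match(tr$product_collapsed, "^S")
  }
})

test_that("with all couplings off the engine is plain adiabatic dynamics", {
  m0 <- small_model(soc_st = 0, soc_tt = 0)
  m0q <- build_model(list(
    states = list(n_singlets = 2L, n_triplets = 2L),
    offsets = list(singlet = c(0.00, 0.30), triplet = c(0.12, 0.35)),
    soc = list(singlet_triplet = 0, intra_triplet = 0),
    nac = list(amplitude = 0),
    bath = list(n = 1L, mass = 1.0, period = 47.0),
    hop_mask = character(0)
  ))
  ic <- sample_initial_conditions(m0q, seed = 2)
  tr <- run_trajectory(m0q, ic, small_params(t_max = 100))
  expect_equal(nrow(tr$hops), 0)
  expect_equal(length(unique(tr$steps$active_diag)), 1)
})
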