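# Shared model builders and a cached small ensemble for the test suite.
# The reduced model (2 singlets + 2 triplets, one bath mode) keeps the
# ensemble-level tests fast while exercising every engine code path.

small_model <- function(soc_st = 0.010, soc_tt = 0.002) {
  build_model(list(
    states = list(n_singlets = 2L, n_triplets = 2L),
    offsets = list(singlet = c(0.00, 0.30), triplet = c(0.12, 0.35)),
    soc = list(singlet_triplet = soc_st, intra_triplet = soc_tt),
    bath = list(n = 1L, mass = 1.0, period = 47.0),
    hop_mask = character(0)
  ))
}

small_params <- function(t_max = 250, ...) {
  engine_params(t_max = t_max, ...)
}

.test_cache <- new.env(parent = emptyenv())

# One reduced-model ensemble reused by several ensemble-level tests.
shared_small_ensemble <- function() {
  if (is.null(.test_cache$ens)) {
    .test_cache$ens <- run_ensemble(small_model(), 30, small_params(),
                                    master_seed = 101)
  }
  .test_cache$ens
}

# Independent brute-force peak counter: explicit per-peak walks, used as
# an oracle against the packaged implementation.
brute_force_peak_count <- function(r, min_prominence) {
  n <- length(r)
  count <- 0L
  if (n < 3) return(count)
  for (i in 2:(n - 1)) {
    if (!(r[i] > r[i - 1] && r[i] > r[i + 1])) next
    lbase <- r[i]; j <- i - 1
    lmin <- Inf
    while (j >= 1) {
      if (r[j] > r[i]) break
      lmin <- min(lmin, r[j]); j <- j - 1
    }
    lbase <- if (is.finite(lmin)) lmin else r[i]
    rbase <- r[i]; j <- i + 1
    rmin <- Inf
    while (j <= n) {
      if (r[j] > r[i]) break
      rmin <- min(rmin, r[j]); j <- j + 1
    }
    rbase <- if (is.finite(rmin)) rmin else r[i]
    if (r[i] - max(lbase, rbase) >= min_prominence) count <- count + 1L
  }
  count
}
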