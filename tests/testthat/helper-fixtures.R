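# Shared fixtures.  Kernels are comparatively expensive to build (dense-grid
# convolutions), so the standard ones are constructed once per test run.

# the classical P = 6 E-spline: alpha = i*pi*(-1/2, -1/3, -1/6, 0, 1/6, 1/3, 1/2)
fig6_grid <- frequency_grid(6, lambda = pi / 6)
fig6_kernel <- make_espline(fig6_grid)

# critical-rate kernel for K = 4 events (P + 1 = 2K), window N = 24 samples
crit_grid <- frequency_grid(7, N = 24)
crit_kernel <- make_espline(crit_grid)

# roomier kernel for pencil / estimate_K checks
wide_grid <- frequency_grid(9, N = 24)
wide_kernel <- make_espline(wide_grid)

gauss1 <- make_gaussian(1)

# moments synthesized directly from (b, u): the forward model of the
# annihilating-filter recovery, used as an independent oracle
synth_moments <- function(b, u, P) {
  vapply(0:P, function(m) sum(b * u^m), complex(1))
}

sort_by_arg <- function(u) u[order(Arg(u))]

# random well-separated event configuration in [lo, hi] (units of T)
random_events <- function(K, lo, hi, min_gap, T = 1) {
  repeat {
    tk <- sort(stats::runif(K, lo, hi))
    if (K < 2L || min(diff(tk)) > min_gap) return(tk * T)
  }
}

expect_events_equal <- function(rec, times, amps = NULL, tol_t, T = 1,
                                tol_a = NULL) {
  expect_equal(nrow(rec$events), length(times))
  expect_lt(max(abs(rec$events$t - times)) / T, tol_t)
  if (!is.null(amps)) {
    expect_lt(max(abs(rec$events$a - amps)), tol_a %||% tol_t)
  }
}
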