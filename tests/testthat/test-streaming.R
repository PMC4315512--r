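# Sliding-window detection, location histograms, peak extraction, and the
# double-consistency spike search.

Tper <- 1 / 16

make_stream_samples <- function(times, amps, kernel, Tper, snr_db = Inf,
                                pad = 40L, seed = NULL) {
  st <- dirac_stream(times, amps)
  tau <- times / Tper
  nr <- c(floor(min(tau)) - pad, ceiling(max(tau)) + pad)
  y <- sample_diracs(st, kernel, Tper, n_range = nr)
  if (is.finite(snr_db)) y <- add_noise(y, snr_db, seed = seed)
  y
}

test_that("every fully capturing window recovers a lone Dirac exactly", {
  g <- frequency_grid(7, N = 20)
  k <- make_espline(g)
  cfg <- window_config(N = 20, T = Tper, kernel = k, P = 7, K_max = 2,
                       denoise = FALSE)
  y <- make_stream_samples(1.0, 1, k, Tper, pad = 30L)
  det <- sliding_window_detect(y, cfg)
  kept <- det$estimates[det$estimates$retained, ]
  # one estimate per fully-capturing window position, all at t = 1.0
  expect_gte(nrow(kept), cfg$windows_per_event)
  expect_lt(max(abs(kept$t - 1.0)) / Tper, 1e-6)
  expect_lt(max(abs(kept$a - 1)), 1e-5)
})

test_that("border events perturb a window but not windows fully past them", {
  g <- frequency_grid(7, N = 20)
  k <- make_espline(g)
  L <- k$P + 1L
  y <- make_stream_samples(c(1.0, 2.5), c(1, 1), k, Tper, pad = 40L)
  cfg <- window_config(N = 20, T = Tper, kernel = k, P = 7, K_max = 1,
                       denoise = FALSE)
  det <- sliding_window_detect(y, cfg)
  est <- det$estimates
  # windows starting past the first event's influenced samples and fully
  # capturing the second see only the second: their estimates sit on it
  tau1 <- 1 / Tper
  tau2 <- 2.5 / Tper
  clean <- est[est$window >= tau1 + 1 & est$window <= tau2 - L + 1, ]
  clean <- clean[clean$retained, ]
  expect_gt(nrow(clean), 0)
  expect_lt(max(abs(clean$t - 2.5)) / Tper, 1e-6)
  # windows straddling the first event's influence are border-affected:
  # their estimates do not all sit on either true location
  border <- est[est$window > 1 / Tper - L & est$window < 1 / Tper, ]
  expect_gt(nrow(border), 0)
  expect_gt(max(pmin(abs(border$t - 1.0), abs(border$t - 2.5))) / Tper, 0.1)
})

test_that("an all-zero noiseless stream yields no estimates", {
  g <- frequency_grid(7, N = 20)
  k <- make_espline(g)
  cfg <- window_config(N = 20, T = Tper, kernel = k, P = 7)
  y <- sample_sequence(rep(0, 60), Tper)
  det <- sliding_window_detect(y, cfg)
  expect_identical(nrow(det$estimates), 0L)
  h <- build_histogram(det, bin_width = Tper / 4)
  expect_true(all(h$counts == 0))
})

test_that("histograms count retained locations and respect the horizon", {
  df <- data.frame(window = 1L, t = c(rep(1.003, 7), 2.2, 9.9),
                   a = 1, u_mod = 1,
                   retained = c(rep(TRUE, 8), TRUE))
  h <- build_histogram(df, bin_width = 0.1)
  expect_identical(sum(h$counts), 9L)
  expect_identical(max(h$counts), 7L)   # the repeated location in one bin
  h2 <- build_histogram(df, bin_width = 0.1, t_max_consistent = 5)
  expect_identical(sum(h2$counts), 8L)
  expect_error(build_histogram(df, bin_width = 0), "positive")
})

test_that("peak extraction thresholds, merges, and ignores a low noise floor", {
  # single sharp peak
  df <- data.frame(t = rep(1.0, 20), retained = TRUE)
  h <- build_histogram(df, bin_width = 0.05)
  pk <- extract_peaks(h, max_count = 20, min_count_frac = 0.3)
  expect_length(pk$times, 1)
  expect_lt(abs(pk$times - 1.0), 0.05)

  # two nearby peaks merge to the count-weighted centroid
  df2 <- data.frame(t = c(rep(1.0, 12), rep(1.06, 6)), retained = TRUE)
  h2 <- build_histogram(df2, bin_width = 0.05)
  pk2 <- extract_peaks(h2, max_count = 20, min_count_frac = 0.3,
                       min_separation = 0.2)
  expect_length(pk2$times, 1)
  expect_lt(abs(pk2$times - (12 * 1.025 + 6 * 1.075) / 18), 0.02)

  # uniform sub-threshold floor: no spikes
  df3 <- data.frame(t = seq(0.1, 3, by = 0.11), retained = TRUE)
  h3 <- build_histogram(df3, bin_width = 0.05)
  pk3 <- extract_peaks(h3, max_count = 20, min_count_frac = 0.3)
  expect_length(pk3$times, 0)

  expect_error(extract_peaks(h3, 20, min_count_frac = 0), "min_count_frac")
})

test_that("histogram total counts are bounded by windows x K_max", {
  g <- frequency_grid(7, N = 20)
  k <- make_espline(g)
  cfg <- window_config(N = 20, T = Tper, kernel = k, P = 7, K_max = 2)
  y <- make_stream_samples(c(0.7, 1.9), c(1, 1), k, Tper, snr_db = 15,
                           pad = 30L, seed = 5)
  det <- sliding_window_detect(y, cfg)
  h <- build_histogram(det, bin_width = Tper / 4)
  expect_lte(sum(h$counts), det$n_windows * cfg$K_max)
})

test_that("double consistency localizes a noiseless decaying exponential", {
  alpha <- 2
  es <- exponential_stream(1.37, 1, alpha = alpha)
  g <- frequency_grid(7, N = 24)
  k <- make_espline(g)
  y <- sample_stream(es, k, Tper, n_range = c(-30, 90))
  psi <- effective_kernel(k, alpha, Tper)
  cfg_big <- window_config(N = 24, T = Tper, kernel = psi, P = 7, K_max = 2)
  cfg_small <- window_config(N = 12, T = Tper, kernel = psi, P = 3,
                             K_fixed = TRUE)
  res <- double_consistency(y, cfg_big, cfg_small, alpha = alpha)
  expect_length(res$spikes$times, 1)
  expect_lt(abs(res$spikes$times - 1.37), res$histogram$bin_width)

  expect_error(double_consistency(y, cfg_big, cfg_big, alpha = alpha),
               "K = 1")
})

test_that("double consistency is invariant to integer-sample time shifts", {
  alpha <- 2
  shift <- 16L   # one second
  g <- frequency_grid(7, N = 24)
  k <- make_espline(g)
  run <- function(t0, nlo) {
    es <- exponential_stream(t0, 1, alpha = alpha)
    y <- sample_stream(es, k, Tper, n_range = c(nlo, nlo + 120))
    psi <- effective_kernel(k, alpha, Tper)
    cfg_big <- window_config(N = 24, T = Tper, kernel = psi, P = 7, K_max = 2)
    cfg_small <- window_config(N = 12, T = Tper, kernel = psi, P = 3,
                               K_fixed = TRUE)
    double_consistency(y, cfg_big, cfg_small, alpha = alpha)$spikes$times
  }
  t1 <- run(1.37, -30L)
  t2 <- run(1.37 + shift * Tper, -30L + shift)
  expect_equal(t2 - shift * Tper, t1, tolerance = 1e-9)
})

test_that("spikes are recovered from synthetic calcium traces at moderate SNR", {
  tau_ca <- 0.5
  n_ok_count <- 0L
  n_ok_time <- 0L
  trials <- 5L
  for (i in seq_len(trials)) {
    spk <- gen_poisson_spikes(0.4, 20, refractory = 0.5, seed = 300 + i)
    if (length(spk$times) < 2) spk <- spike_train(c(4.3, 11.7))
    model <- calcium_model(A = 1, tau_ca = tau_ca, snr_db = 20)
    trc <- gen_calcium_trace(spk, model, T = Tper, n_samples = 22L * 16L,
                             seed = 400 + i)
    res <- infer_spikes(trc$trace, tau_ca = tau_ca)
    est <- res$spikes$times
    if (length(est) == length(spk$times)) {
      n_ok_count <- n_ok_count + 1L
      if (max(abs(est - spk$times)) <= 2 * Tper) n_ok_time <- n_ok_time + 1L
    }
  }
  # majority of seeded trials recover the exact count with |dt| <= 2T
  expect_gte(n_ok_count, 3L)
  expect_gte(n_ok_time, 3L)
})
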