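# Sequential sliding-window reconstruction of streaming FRI signals and the
# location-histogram consistency analysis used for spike inference.
#
# A window of N samples is analysed at every position (advance = one sampling
# interval by default).  Windows that fully capture an event recover it
# exactly in the noiseless case; windows contaminated by border events
# scatter.  Pooling the per-window location estimates into a histogram makes
# the consistent estimates pile up into peaks at the true locations.

#' Sliding-window configuration
#'
#' @param N samples per window; the window duration is `tau = N * T`.
#' @param T sampling period in seconds.
#' @param kernel the acquisition kernel the samples were taken with (for the
#'   finite-difference path, the effective kernel \eqn{\psi}).
#' @param P moment order for the per-window frequency grid (default
#'   `lambda = 2*pi/N`, symmetric).
#' @param K_max maximum number of events per window; with `K_fixed = TRUE`
#'   every window is solved with `K = 1` instead of estimating `K`.
#' @param K_fixed logical; fix `K = 1` per window (the small-window mode of
#'   the double-consistency search).
#' @param step window advance in samples.
#' @param coeff_mode `"exact"` (Strang-Fix kernels) or `"cls"`.
#' @param denoise apply [cadzow()] before root extraction.
#' @param mu0 singular-value threshold for [estimate_K()].
#' @param u_tol estimates with `|u_k|` outside `1 +/- u_tol` are discarded
#'   before histogramming (border/noise artifacts).
#' @param cadzow_iter Cadzow sweep limit.
#' @param zero_tol windows whose peak magnitude is below `zero_tol` times the
#'   stream's peak magnitude are skipped: they carry no events, only numerical
#'   residue, which would otherwise produce spuriously consistent estimates in
#'   noiseless data.
#' @return An object of class `window_config`.
#' @export
window_config <- function(N, T, kernel, P = 13L, K_max = 5L, K_fixed = FALSE,
                          step = 1L, coeff_mode = c("exact", "cls"),
                          denoise = TRUE, mu0 = 0.3, u_tol = 0.2,
                          cadzow_iter = 20L, zero_tol = 1e-8) {
  coeff_mode <- match.arg(coeff_mode)
  if (N < 2L) stop("N must be at least 2")
  if (P + 1L < 2L) stop("P must be at least 1")
  grid <- frequency_grid(P, N = N)
  co <- if (coeff_mode == "exact") {
    reproduction_coeffs(kernel, grid, c(0L, N - 1L))
  } else {
    approx_coeffs(kernel, grid, c(0L, N - 1L))
  }
  span <- kernel$t_hi - kernel$t_lo
  structure(list(
    N = as.integer(N), T = T, kernel = kernel, grid = grid, coeffs = co,
    P = as.integer(P), K_max = as.integer(K_max), K_fixed = isTRUE(K_fixed),
    step = as.integer(step), coeff_mode = coeff_mode, denoise = isTRUE(denoise),
    mu0 = mu0, u_tol = u_tol, cadzow_iter = as.integer(cadzow_iter),
    zero_tol = zero_tol,
    # full-capture zone for the relative location r = t/T - n0, and the
    # number of window positions that fully capture one event
    r_lo = kernel$t_hi - 1, r_hi = N - 1 + kernel$t_lo,
    windows_per_event = max(0L, floor((N + 1 - span) / step))
  ), class = "window_config")
}

#' @export
print.window_config <- function(x, ...) {
  cat(sprintf("<window_config> N = %d, T = %g, P = %d, %s, step = %d\n",
              x$N, x$T, x$P,
              if (x$K_fixed) "K = 1 fixed" else sprintf("K <= %d estimated", x$K_max),
              x$step))
  invisible(x)
}

#' Sliding-window detection
#'
#' Runs the moment/annihilating-filter pipeline on every window position.
#' Per-window estimates are mapped to absolute time via the window offset;
#' estimates are `retained` when the root modulus is close to the unit circle
#' and the location falls in the window's full-capture zone (locations outside
#' it are border-affected and are kept only as flagged rows).  Per-window
#' numerical failures are recorded and skipped, never abort the stream.
#'
#' @param samples a [sample_sequence()] (at least `N` samples).
#' @param config a [window_config()].
#' @return A list of class `window_estimates`: `estimates` (data frame with
#'   `window`, `t`, `a`, `u_mod`, `retained`), `n_windows`, `n_failures`,
#'   `config`.
#' @export
sliding_window_detect <- function(samples, config) {
  stopifnot(inherits(samples, "sample_seq"), inherits(config, "window_config"))
  y <- samples$values
  N <- config$N
  if (length(y) < N) stop("need at least N samples")
  lam <- config$grid$lambda
  Tper <- samples$T
  starts <- seq.int(1L, length(y) - N + 1L, by = config$step)
  rows <- vector("list", length(starts))
  failures <- 0L
  floor_mag <- config$zero_tol * max(abs(y))
  for (ii in seq_along(starts)) {
    wi <- starts[ii]
    n0 <- samples$n_start + wi - 1L
    yw <- y[wi:(wi + N - 1L)]
    if (max(abs(yw)) <= floor_mag) next
    est <- tryCatch({
      s <- drop(config$coeffs %*% yw)
      K <- if (config$K_fixed) 1L else {
        min(estimate_K(s, config$mu0), config$K_max,
            floor((config$P + 1L) / 2L))
      }
      if (config$denoise) s <- cadzow(s, K, max_iter = config$cadzow_iter)
      h <- tls_annihilator(s, K)
      u <- if (K == 1L) -h[2L] else {
        comp <- rbind(-h[-1L],
                      cbind(diag(1 + 0i, K - 1L), complex(length.out = K - 1L)))
        eigen(comp, only.values = TRUE)$values
      }
      V <- outer(0:config$P, seq_along(u), function(m, k) u[k]^m)
      b <- cls_solve(V, s)
      theta <- Arg(u)
      theta[theta < 0] <- theta[theta < 0] + 2 * pi
      r <- theta / lam
      a <- Re(b * exp(-1i * config$grid$omega0 * r))
      data.frame(
        window = n0, t = (n0 + r) * Tper, a = a, u_mod = Mod(u),
        retained = abs(Mod(u) - 1) <= config$u_tol &
          r >= config$r_lo & r <= config$r_hi
      )
    }, error = function(e) NULL)
    if (is.null(est)) failures <- failures + 1L else rows[[ii]] <- est
  }
  est <- do.call(rbind, rows) %||%
    data.frame(window = integer(), t = numeric(), a = numeric(),
               u_mod = numeric(), retained = logical())
  structure(list(estimates = est, n_windows = length(starts),
                 n_failures = failures, config = config),
            class = "window_estimates")
}

#' Location histogram of sliding-window estimates
#'
#' Bins the retained location estimates.  Estimates at or beyond
#' `t_max_consistent` are excluded: during streaming, only locations no longer
#' influencing the current samples are final (for the last window position
#' `n_i` that horizon is `(n_i - L) * T`).
#'
#' @param estimates a `window_estimates` object (or data frame with columns
#'   `t` and `retained`).
#' @param bin_width histogram bin width in seconds.
#' @param t_max_consistent upper time limit (default `Inf`: offline analysis
#'   of a finite recording).
#' @return An object of class `location_histogram` with `bin_edges`, `counts`,
#'   `bin_width`.
#' @export
build_histogram <- function(estimates, bin_width, t_max_consistent = Inf) {
  if (bin_width <= 0) stop("bin_width must be positive")
  df <- if (inherits(estimates, "window_estimates")) estimates$estimates else estimates
  t <- df$t[df$retained & df$t < t_max_consistent]
  if (!length(t)) {
    edges <- c(0, bin_width)
    return(structure(list(bin_edges = edges, counts = 0L,
                          bin_width = bin_width), class = "location_histogram"))
  }
  lo <- floor(min(t) / bin_width) * bin_width
  hi <- ceiling(max(t) / bin_width + 1e-9) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  idx <- pmin(pmax(floor((t - lo) / bin_width) + 1L, 1L), length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts, bin_width = bin_width),
            class = "location_histogram")
}

#' @export
plot.location_histogram <- function(x, ...) {
  centers <- (x$bin_edges[-1L] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::plot(centers, x$counts, type = "h", xlab = "t (s)",
                 ylab = "count", ...)
  invisible(x)
}

#' Extract spikes from the peaks of a location histogram
#'
#' Local maxima with count at least `min_count_frac` times `max_count` (the
#' number of window positions that can fully capture one location) are peak
#' candidates; candidates closer than `min_separation` are merged into their
#' count-weighted centroid.
#'
#' @param hist a [build_histogram()] result.
#' @param max_count achievable window count per event (see
#'   `window_config()$windows_per_event`; for a joint histogram, the sum over
#'   passes).
#' @param min_count_frac threshold fraction in (0, 1].
#' @param min_separation merge radius in seconds (default `3 * bin_width`).
#' @return A [spike_train()]; amplitudes hold the pooled peak counts.
#' @export
extract_peaks <- function(hist, max_count, min_count_frac = 0.3,
                          min_separation = NULL) {
  stopifnot(inherits(hist, "location_histogram"))
  if (min_count_frac <= 0 || min_count_frac > 1) {
    stop("min_count_frac must be in (0, 1]")
  }
  min_separation <- min_separation %||% (3 * hist$bin_width)
  cnt <- hist$counts
  centers <- (hist$bin_edges[-1L] + hist$bin_edges[-length(hist$bin_edges)]) / 2
  thr <- min_count_frac * max_count
  nb <- length(cnt)
  is_max <- vapply(seq_len(nb), function(i) {
    cnt[i] >= (if (i > 1L) cnt[i - 1L] else 0L) &&
      cnt[i] >= (if (i < nb) cnt[i + 1L] else 0L)
  }, logical(1))
  cand <- which(cnt >= thr & is_max & cnt > 0L)
  times <- numeric(0)
  weights <- numeric(0)
  for (i in cand) {
    j <- length(times)
    if (j && abs(centers[i] - times[j]) < min_separation) {
      tot <- weights[j] + cnt[i]
      times[j] <- (times[j] * weights[j] + centers[i] * cnt[i]) / tot
      weights[j] <- tot
    } else {
      times <- c(times, centers[i])
      weights <- c(weights, cnt[i])
    }
  }
  spike_train(times, weights)
}

#' Double-consistency spike search
#'
#' Runs the sliding-window detector twice -- once with a large window where
#' the number of events per window is estimated from the moment singular
#' values, once with a small window where `K = 1` is assumed -- pools all
#' retained location estimates into one joint histogram, and takes the spikes
#' from its peaks.  For decaying-exponential inputs (e.g. calcium traces),
#' pass `alpha` to apply the finite-difference reduction first; both window
#' configurations must then be built on the corresponding
#' [effective_kernel()].
#'
#' @param samples a [sample_sequence()].
#' @param config_big a [window_config()] with `K` estimation.
#' @param config_small a [window_config()] with `K_fixed = TRUE`.
#' @param alpha optional decay rate; when given, [finite_difference()] is
#'   applied before windowing.
#' @param bin_width histogram bin width (default `T / 4`).
#' @param min_count_frac peak threshold fraction.
#' @param min_amp_frac amplitude gate: retained estimates whose `|a|` falls
#'   below this fraction of the pooled 0.9 amplitude quantile are discarded
#'   before histogramming (0 disables).  Useful when all events share one
#'   amplitude, as in the calcium model, where noise-only windows yield
#'   near-zero amplitudes.
#' @param t_max_consistent histogram horizon (default `Inf`).
#' @return A list of class `spike_search`: `spikes` ([spike_train()]),
#'   `histogram`, and the two `window_estimates` passes.
#' @export
double_consistency <- function(samples, config_big, config_small, alpha = NULL,
                               bin_width = NULL, min_count_frac = 0.3,
                               min_amp_frac = 0, t_max_consistent = Inf) {
  if (config_small$K_fixed != TRUE) {
    stop("config_small must use the fixed K = 1 mode")
  }
  if (config_big$K_fixed) stop("config_big must estimate K per window")
  if (!is.null(alpha)) samples <- finite_difference(samples, alpha)
  bin_width <- bin_width %||% (samples$T / 4)
  pass_big <- sliding_window_detect(samples, config_big)
  pass_small <- sliding_window_detect(samples, config_small)
  pooled <- rbind(pass_big$estimates, pass_small$estimates)
  if (min_amp_frac > 0 && any(pooled$retained)) {
    ref <- stats::quantile(abs(pooled$a[pooled$retained]), 0.9, names = FALSE)
    pooled$retained <- pooled$retained & abs(pooled$a) >= min_amp_frac * ref
  }
  hist <- build_histogram(pooled, bin_width, t_max_consistent)
  max_count <- config_big$windows_per_event + config_small$windows_per_event
  spikes <- extract_peaks(hist, max_count, min_count_frac)
  structure(list(spikes = spikes, histogram = hist,
                 pass_big = pass_big, pass_small = pass_small,
                 max_count = max_count),
            class = "spike_search")
}

#' Infer spikes from a calcium fluorescence trace
#'
#' End-to-end wrapper for instantaneously sampled fluorescence: optional
#' baseline removal (median subtraction), finite differences with the calcium
#' decay rate, and the double-consistency spike search with the zero-order
#' effective kernel and constant least-squares coefficients.
#'
#' @param trace a [sample_sequence()] of fluorescence values.
#' @param tau_ca calcium decay time constant in seconds.
#' @param N_big,P_big large-window size and moment order.
#' @param N_small,P_small small-window (fixed `K = 1`) size and order.
#' @param K_max cap on events per large window.
#' @param baseline `"median"` subtracts the median before differencing,
#'   `"none"` leaves the trace as is.
#' @param mu0,min_count_frac,bin_width tuning knobs passed through.
#' @param min_amp_frac amplitude gate (see [double_consistency()]); on by
#'   default since the calcium model assumes a common jump amplitude.
#' @return A `spike_search` result (see [double_consistency()]).
#' @export
infer_spikes <- function(trace, tau_ca, N_big = 32L, P_big = 8L,
                         N_small = 8L, P_small = 3L, K_max = 3L,
                         baseline = c("median", "none"), mu0 = 0.3,
                         min_count_frac = 0.3, bin_width = NULL,
                         min_amp_frac = 0.3) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(trace, "sample_seq"))
  if (baseline == "median") {
    trace <- sample_sequence(trace$values - stats::median(trace$values),
                             T = trace$T, n_start = trace$n_start,
                             noise_sigma = trace$noise_sigma)
  }
  alpha <- 1 / tau_ca
  psi <- effective_kernel(NULL, alpha, trace$T)
  cfg_big <- window_config(N_big, trace$T, psi, P = P_big, K_max = K_max,
                           coeff_mode = "cls", mu0 = mu0)
  cfg_small <- window_config(N_small, trace$T, psi, P = P_small,
                             K_fixed = TRUE, coeff_mode = "cls")
  double_consistency(trace, cfg_big, cfg_small, alpha = alpha,
                     bin_width = bin_width, min_count_frac = min_count_frac,
                     min_amp_frac = min_amp_frac)
}
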