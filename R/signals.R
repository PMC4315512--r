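# Continuous-time FRI signal models and synthetic ground-truth generators.

#' Stream of Diracs
#'
#' A finite stream \eqn{x(t) = \sum_k a_k \delta(t - t_k)} described by its
#' event times and amplitudes.  Times must be strictly increasing (distinct
#' delays are required for uniqueness of the annihilating-filter recovery).
#'
#' @param times event times in seconds (strictly increasing).
#' @param amplitudes real amplitudes (recycled scalar allowed).
#' @return An object of class `dirac_stream`.
#' @export
dirac_stream <- function(times, amplitudes = 1) {
  check_events(times)
  amplitudes <- rep_len(as.numeric(amplitudes), length(times))
  structure(list(times = as.numeric(times), amplitudes = amplitudes,
                 K = length(times)),
            class = "dirac_stream")
}

#' Stream of decaying exponentials
#'
#' \eqn{x(t) = \sum_k a_k e^{-\alpha (t - t_k)} 1_{t \ge t_k}}: each event
#' launches a one-sided exponential tail with common decay rate `alpha`
#' (the calcium-transient model has \eqn{\alpha = 1/\tau_{ca}}).
#'
#' @inheritParams dirac_stream
#' @param alpha positive decay rate in 1/seconds.
#' @return An object of class `exp_stream`.
#' @export
exponential_stream <- function(times, amplitudes = 1, alpha) {
  check_events(times)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be a positive scalar")
  }
  amplitudes <- rep_len(as.numeric(amplitudes), length(times))
  structure(list(times = as.numeric(times), amplitudes = amplitudes,
                 alpha = alpha, K = length(times)),
            class = "exp_stream")
}

check_events <- function(times) {
  if (length(times) && any(diff(times) <= 0)) {
    stop("event times must be strictly increasing (all t_k distinct)")
  }
  invisible(times)
}

#' Spike train
#'
#' A sorted list of inferred or ground-truth event times, with optional
#' amplitudes.
#'
#' @param times event times in seconds (sorted ascending).
#' @param amplitudes optional amplitudes.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, amplitudes = NULL) {
  times <- as.numeric(times)
  if (is.unsorted(times)) stop("spike times must be sorted ascending")
  if (!is.null(amplitudes)) amplitudes <- rep_len(as.numeric(amplitudes), length(times))
  structure(list(times = times, amplitudes = amplitudes), class = "spike_train")
}

#' Calcium transient model parameters
#'
#' Fluorescence is modelled as the spike train convolved with a one-sided
#' decaying exponential of amplitude `A` and time constant `tau_ca`, plus
#' additive white Gaussian noise.  Noise is parameterized either by its
#' standard deviation or by the per-sample signal-to-noise ratio in dB
#' (`SNR = 10 log10(mean(clean^2) / sigma^2)`).
#'
#' @param A transient jump amplitude (fluorescence units), positive.
#' @param tau_ca decay time constant in seconds, positive.
#' @param snr_db per-sample SNR in dB (`Inf` for noiseless), or `NULL` if
#'   `noise_sigma` is given.
#' @param noise_sigma noise standard deviation, or `NULL`.
#' @param baseline constant fluorescence baseline added to the trace.
#' @return An object of class `calcium_model`.
#' @export
calcium_model <- function(A = 1, tau_ca = 0.5, snr_db = Inf,
                          noise_sigma = NULL, baseline = 0) {
  if (A <= 0 || tau_ca <= 0) stop("A and tau_ca must be positive")
  structure(list(A = A, tau_ca = tau_ca, snr_db = snr_db,
                 noise_sigma = noise_sigma, baseline = baseline),
            class = "calcium_model")
}

#' Evaluate a decaying-exponential stream pointwise
#'
#' @param stream an [exponential_stream()].  Dirac streams are distributional
#'   and cannot be evaluated pointwise.
#' @param t numeric vector of times in seconds.
#' @return The sum of the one-sided exponential tails at `t`.
#' @export
evaluate_stream <- function(stream, t) {
  if (inherits(stream, "dirac_stream")) {
    stop("a Dirac stream is distributional and has no pointwise values")
  }
  stopifnot(inherits(stream, "exp_stream"))
  out <- numeric(length(t))
  for (k in seq_len(stream$K)) {
    dt <- t - stream$times[k]
    out <- out + stream$amplitudes[k] * exp(-stream$alpha * dt) * (dt >= 0)
  }
  out
}

#' Generate a Poisson spike train with refractory thinning
#'
#' Homogeneous Poisson arrivals at the given rate, thinned so that successive
#' retained spikes are at least `refractory` seconds apart (on a conflict the
#' earlier spike is kept, which is deterministic and order-preserving).
#'
#' @param rate mean firing rate in events/second (before thinning).
#' @param duration recording length in seconds.
#' @param refractory minimum inter-spike interval in seconds.
#' @param seed optional RNG seed for reproducibility.
#' @return A [spike_train()].
#' @export
gen_poisson_spikes <- function(rate, duration, refractory = 0, seed = NULL) {
  if (rate <= 0) stop("rate must be positive")
  if (refractory < 0) stop("refractory must be nonnegative")
  with_seed(seed, {
    n <- stats::rpois(1L, rate * duration)
    arr <- sort(stats::runif(n, 0, duration))
    keep <- numeric(0)
    last <- -Inf
    for (t in arr) {
      if (t - last >= refractory) {
        keep <- c(keep, t)
        last <- t
      }
    }
    spike_train(keep)
  })
}

#' Generate a synthetic calcium fluorescence trace
#'
#' Instantaneous uniform samples of
#' \eqn{c(t) = A \sum_k e^{-(t - t_k)/\tau_{ca}} 1_{t \ge t_k} +
#' \mathrm{baseline} + \varepsilon_t}
#' with i.i.d. Gaussian noise whose variance is set from the model's
#' `noise_sigma` or per-sample `snr_db` (computed on the noiseless samples).
#'
#' @param spikes a [spike_train()] of ground-truth event times.
#' @param model a [calcium_model()].
#' @param T sampling period in seconds.
#' @param n_samples number of samples; sampling times are `(n_start:(n_start +
#'   n_samples - 1)) * T`.
#' @param n_start index of the first sample (default 0).
#' @param seed optional RNG seed for the noise draw.
#' @return A list with the noisy [sample_sequence()] `trace`, the noiseless
#'   `clean` sequence, and the ground-truth `spikes`.
#' @export
gen_calcium_trace <- function(spikes, model, T, n_samples, n_start = 0L,
                              seed = NULL) {
  stopifnot(inherits(spikes, "spike_train"), inherits(model, "calcium_model"))
  if (T <= 0) stop("T must be positive")
  tt <- (n_start + seq_len(n_samples) - 1) * T
  clean <- numeric(n_samples)
  if (length(spikes$times)) {
    stream <- exponential_stream(spikes$times,
                                 amplitudes = model$A,
                                 alpha = 1 / model$tau_ca)
    clean <- evaluate_stream(stream, tt)
  }
  sigma <- model$noise_sigma
  if (is.null(sigma)) {
    sigma <- if (is.infinite(model$snr_db)) 0 else {
      sqrt(mean(clean^2) / 10^(model$snr_db / 10))
    }
  }
  noisy <- with_seed(seed, clean + model$baseline +
                       if (sigma > 0) stats::rnorm(n_samples, 0, sigma) else 0)
  list(
    trace = sample_sequence(noisy, T = T, n_start = n_start, noise_sigma = sigma),
    clean = sample_sequence(clean + model$baseline, T = T, n_start = n_start),
    spikes = spikes
  )
}

#' Rate of innovation of a finite event stream
#'
#' Each event carries two degrees of freedom (location and amplitude), so a
#' stream with `K` events over an interval of length `duration` has rate
#' `2 K / duration`.
#'
#' @param stream a `dirac_stream`, `exp_stream` or `spike_train`.
#' @param duration interval length in seconds.
#' @return The rate of innovation in parameters/second.
#' @export
rate_of_innovation <- function(stream, duration) {
  2 * length(stream$times) / duration
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d events", length(x$times)))
  if (length(x$times)) {
    cat(sprintf(" in [%.4g, %.4g] s", min(x$times), max(x$times)))
  }
  cat("\n")
  invisible(x)
}
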