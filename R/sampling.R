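# The acquisition model: filter x(t) with h(t) = phi(-t/T), sample at t = nT,
# equivalently y_n = <x(t), phi(t/T - n)>, then (optionally) add white noise.

#' Uniform sample sequence
#'
#' @param values numeric vector of samples `y_n`.
#' @param T sampling period in seconds.
#' @param n_start integer index of the first stored sample.
#' @param noise_sigma optional noise standard deviation (recorded metadata).
#' @return An object of class `sample_seq`.
#' @export
sample_sequence <- function(values, T, n_start = 0L, noise_sigma = NULL) {
  if (T <= 0) stop("T must be positive")
  structure(list(values = as.numeric(values), T = T,
                 n_start = as.integer(n_start), noise_sigma = noise_sigma),
            class = "sample_seq")
}

#' @export
print.sample_seq <- function(x, ...) {
  cat(sprintf("<sample_seq> %d samples, T = %g s, n = %d..%d\n",
              length(x$values), x$T, x$n_start,
              x$n_start + length(x$values) - 1L))
  invisible(x)
}

#' @export
as.data.frame.sample_seq <- function(x, ...) {
  n <- x$n_start + seq_along(x$values) - 1L
  data.frame(n = n, time = n * x$T, value = x$values)
}

sample_indices <- function(x) x$n_start + seq_along(x$values) - 1L

# Default index range: every n whose kernel copy overlaps some event.
# phi(t/T - n) is nonzero for t/T - n in [t_lo, t_hi), i.e.
# n in (tau - t_hi, tau - t_lo].
default_n_range <- function(stream, kernel, T, tail_mult = 40) {
  tau <- stream$times / T
  lo <- floor(min(tau) - kernel$t_hi) + 1L
  hi <- floor(max(tau) - kernel$t_lo)
  if (inherits(stream, "exp_stream")) {
    # exponential tails extend to the right; cover until they are negligible
    hi <- hi + ceiling(tail_mult / (stream$alpha * T))
  }
  c(lo, hi)
}

#' Sample a stream of Diracs with a sampling kernel
#'
#' By the sifting property, \eqn{y_n = \sum_k a_k \varphi(t_k/T - n)}: each
#' Dirac influences exactly as many samples as the kernel support spans.
#'
#' @param stream a [dirac_stream()].
#' @param kernel an `fri_kernel`.
#' @param T sampling period in seconds.
#' @param n_range integer range of sample indices (default: the minimal set
#'   with any kernel overlap).
#' @return A [sample_sequence()].
#' @export
sample_diracs <- function(stream, kernel, T, n_range = NULL) {
  stopifnot(inherits(stream, "dirac_stream"), inherits(kernel, "fri_kernel"))
  if (T <= 0) stop("T must be positive")
  n_range <- n_range %||% default_n_range(stream, kernel, T)
  ns <- seq.int(min(n_range), max(n_range))
  tau <- stream$times / T
  y <- numeric(length(ns))
  for (k in seq_len(stream$K)) {
    y <- y + stream$amplitudes[k] * Re(kernel_eval(kernel, tau[k] - ns))
  }
  sample_sequence(y, T = T, n_start = ns[1L])
}

#' Sample a stream of decaying exponentials with a sampling kernel
#'
#' Computes \eqn{y_n = \langle x(t), \varphi(t/T - n)\rangle} by integrating
#' each one-sided exponential tail against the kernel.  The integral is
#' evaluated from a precomputed cumulative integral of
#' \eqn{e^{-\alpha T u}\varphi(u)} on the kernel's dense grid (fourth-order
#' accurate), so the event-time kinks are handled exactly up to grid
#' interpolation.
#'
#' @param stream an [exponential_stream()].
#' @inheritParams sample_diracs
#' @return A [sample_sequence()].
#' @export
sample_stream <- function(stream, kernel, T, n_range = NULL) {
  stopifnot(inherits(stream, "exp_stream"), inherits(kernel, "fri_kernel"))
  if (T <= 0) stop("T must be positive")
  n_range <- n_range %||% default_n_range(stream, kernel, T)
  ns <- seq.int(min(n_range), max(n_range))
  aT <- stream$alpha * T
  h <- kernel$step
  # kernel values on its support grid
  u <- seq(kernel$t_lo, kernel$t_hi, by = h)
  pv <- kernel_eval(kernel, u)
  J <- cumsimp(exp(-aT * u) * pv, h)   # J(v) = int_{t_lo}^{v} e^{-aT u} phi(u) du
  Jfull <- J[length(J)]
  tau <- stream$times / T
  y <- complex(length.out = length(ns))
  for (k in seq_len(stream$K)) {
    v <- tau[k] - ns               # lower integration limit in kernel coords
    Jv <- complex(length.out = length(ns))
    below <- v <= kernel$t_lo
    above <- v >= kernel$t_hi
    mid <- !below & !above
    Jv[below] <- 0
    Jv[above] <- Jfull
    if (any(mid)) {
      Jv[mid] <- interp_nodes(J, kernel$t_lo, h, v[mid])
    }
    y <- y + stream$amplitudes[k] * exp(-aT * (ns - tau[k])) * (Jfull - Jv)
  }
  y <- T * y
  sample_sequence(Re(drop_tiny_imag(y, tol = 1e-7)), T = T, n_start = ns[1L])
}

#' Add white Gaussian noise at a prescribed SNR
#'
#' \eqn{\tilde y_n = y_n + \varepsilon_n} with i.i.d. zero-mean Gaussian
#' \eqn{\varepsilon_n} whose variance is set so that
#' `10 log10(mean(y^2) / sigma^2) = snr_db`.
#'
#' @param samples a [sample_sequence()].
#' @param snr_db requested SNR in dB; `Inf` returns the input unchanged.
#' @param seed optional RNG seed.
#' @return A noisy [sample_sequence()] with `noise_sigma` recorded.
#' @export
add_noise <- function(samples, snr_db, seed = NULL) {
  stopifnot(inherits(samples, "sample_seq"))
  if (!length(samples$values)) stop("samples must be nonempty")
  if (is.infinite(snr_db)) return(samples)
  p <- mean(samples$values^2)
  if (p == 0) stop("cannot set a finite SNR on an all-zero sequence")
  sigma <- sqrt(p / 10^(snr_db / 10))
  with_seed(seed, {
    noisy <- samples$values + stats::rnorm(length(samples$values), 0, sigma)
    sample_sequence(noisy, T = samples$T, n_start = samples$n_start,
                    noise_sigma = sigma)
  })
}
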