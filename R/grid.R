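#' Equispaced symmetric frequency grid
#'
#' The reconstruction machinery retrieves the Fourier transform of the input
#' signal at `P + 1` equispaced purely imaginary exponents
#' \eqn{\omega_m = \omega_0 + \lambda m}, \eqn{m = 0, \dots, P}.  The grid is
#' required to be symmetric (\eqn{\omega_m = -\omega_{P-m}}, hence
#' \eqn{\omega_0 = -\lambda P / 2}) so that the associated E-spline is
#' real-valued, and no two frequencies may differ by a nonzero multiple of
#' \eqn{2\pi} (each frequency places spectral zeros at \eqn{\omega_m + 2\pi l},
#' which must not hit another grid point).
#'
#' With `lambda = 2 * pi / N` the mapping from unit-circle phases back to event
#' times is unambiguous for times within `N` sampling periods, which is why the
#' default ties the spacing to the analysis window length.
#'
#' @param P integer order; the grid has `P + 1` frequencies.
#' @param N window length in samples used to set the default spacing
#'   `lambda = 2 * pi / N`.
#' @param lambda frequency spacing in radians (overrides `N`).
#' @return An object of class `fri_grid` with fields `P`, `omega0`, `lambda`
#'   and the vector `omegas`.
#' @examples
#' g <- frequency_grid(P = 7, N = 32)
#' g$omegas
#' @export
frequency_grid <- function(P, N = NULL, lambda = NULL) {
  if (!is.numeric(P) || length(P) != 1L || P < 0 || P != round(P)) {
    stop("P must be a nonnegative integer")
  }
  P <- as.integer(P)
  if (is.null(lambda)) {
    if (is.null(N)) stop("provide either N or lambda")
    lambda <- 2 * pi / N
  }
  if (lambda <= 0) stop("lambda must be positive")
  omega0 <- -lambda * P / 2
  omegas <- omega0 + lambda * (0:P)
  # no two frequencies may coincide modulo 2*pi
  d <- outer(omegas, omegas, "-") / (2 * pi)
  offdiag <- d[upper.tri(d)]
  if (any(abs(offdiag - round(offdiag)) < 1e-12 & abs(offdiag) > 1e-12) ||
      any(abs(offdiag) < 1e-12)) {
    stop("invalid frequency grid: some omega_m - omega_n is a multiple of 2*pi")
  }
  structure(
    list(P = P, omega0 = omega0, lambda = lambda, omegas = omegas),
    class = "fri_grid"
  )
}

#' @export
print.fri_grid <- function(x, ...) {
  cat(sprintf(
    "<fri_grid> P = %d, lambda = %.6g, omega in [%.6g, %.6g]\n",
    x$P, x$lambda, x$omegas[1L], x$omegas[x$P + 1L]
  ))
  invisible(x)
}
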