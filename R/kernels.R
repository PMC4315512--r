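# Sampling kernels: exponential B-splines (E-splines) and the Gaussian filter.
#
# An E-spline with exponent vector alpha = (alpha_0, ..., alpha_P) is the
# P-fold convolution of the zero-order factors e^{alpha_m t} 1_[0,1)(t); its
# Fourier transform is the product of the factors
# (1 - e^{alpha_m - i w}) / (i w - alpha_m).  It has compact support [0, P+1)
# and, together with its integer shifts, reproduces the exponentials
# e^{alpha_m t} exactly (generalised Strang-Fix conditions).  The Gaussian
# violates the Strang-Fix conditions but its spectral leakage at
# omega_m + 2 pi l is so small that approximate reproduction is still very
# accurate (constant least-squares coefficients).

espline_step_default <- 2^-12

# order-0 E-spline: e^{a t} on [0, 1)
espline0_eval <- function(a, t) {
  out <- complex(length.out = length(t))
  i <- t >= 0 & t < 1
  out[i] <- exp(a * t[i])
  out
}

# order-1 E-spline (two factors), exact piecewise closed form on [0, 2)
espline1_eval <- function(a0, a1, t) {
  out <- complex(length.out = length(t))
  i1 <- t >= 0 & t < 1
  i2 <- t >= 1 & t < 2
  if (abs(a0 - a1) < 1e-9) {
    a <- (a0 + a1) / 2
    out[i1] <- t[i1] * exp(a * t[i1])
    out[i2] <- (2 - t[i2]) * exp(a * t[i2])
  } else {
    d <- a0 - a1
    out[i1] <- (exp(a0 * t[i1]) - exp(a1 * t[i1])) / d
    out[i2] <- (exp(a1 * (t[i2] - 1)) * exp(a0) -
                exp(a0 * (t[i2] - 1)) * exp(a1)) / d
  }
  out
}

# Dense-grid values of the E-spline with exponents `alpha` at nodes
# (0:M)*step.  Orders 0 and 1 are exact; higher orders are built by repeated
# convolution with one zero-order factor using the identity
#   (f * beta_a)(t) = e^{a t} (g(t) - g(t - 1)),  g(t) = int_0^t e^{-a u} f(u) du,
# with the cumulative integral evaluated by a fourth-order rule.
espline_grid_values <- function(alpha, step) {
  m <- round(1 / step)
  if (abs(1 / step - m) > 1e-9) stop("eval_grid_step must divide 1 exactly")
  P <- length(alpha) - 1L
  if (P == 0L) {
    v <- espline0_eval(alpha[1L], seq(0, 1, by = step))
    return(v)
  }
  v <- espline1_eval(alpha[1L], alpha[2L], seq(0, 2, by = step))
  if (P >= 2L) {
    for (j in 3:(P + 1L)) {
      a <- alpha[j]
      tt <- seq_along(v) - 1
      g <- cumsimp(exp(-a * tt * step) * v, step)
      nlen <- length(v) + m
      tnew <- (seq_len(nlen) - 1) * step
      v <- exp(a * tnew) * (c(g, rep(g[length(g)], m)) - c(rep(0 + 0i, m), g))
    }
  }
  v
}

new_kernel <- function(family, ...) {
  structure(c(list(family = family), list(...)), class = "fri_kernel")
}

#' Construct an E-spline sampling kernel
#'
#' Builds the exponential B-spline with exponent vector `alpha`, i.e. the
#' convolution of the zero-order factors \eqn{e^{\alpha_m t} 1_{[0,1)}(t)}.
#' The kernel has support `[0, P + 1)` where `P = length(alpha) - 1`.  It is
#' real-valued exactly when the exponents are real or occur in complex
#' conjugate pairs (the usual choice: purely imaginary, symmetric about 0).
#'
#' Evaluation uses exact closed forms for orders 0 and 1 and repeated
#' numerical convolution on a dense uniform grid for higher orders; off-grid
#' queries are interpolated.
#'
#' @param alpha complex vector of exponents (length `P + 1`); a
#'   [frequency_grid()] may be passed instead, in which case
#'   `alpha = 1i * grid$omegas`.
#' @param step internal evaluation grid step in normalized-time units; must
#'   divide 1 exactly.  Smaller values give more accurate evaluation.
#' @return An object of class `fri_kernel`.
#' @examples
#' box <- make_espline(0)              # the box function on [0, 1)
#' tri <- make_espline(c(0, 0))        # the triangle (hat) on [0, 2)
#' g <- frequency_grid(6, lambda = pi / 6)
#' es <- make_espline(g)               # the classical P = 6 imaginary grid
#' @export
make_espline <- function(alpha, step = espline_step_default) {
  if (inherits(alpha, "fri_grid")) alpha <- 1i * alpha$omegas
  if (length(alpha) == 0L) stop("alpha must be a nonempty exponent vector")
  alpha <- as.complex(alpha)
  P <- length(alpha) - 1L
  v <- espline_grid_values(alpha, step)
  # exponent multisets closed under conjugation give real kernels
  is_real <- max(Mod(sort_complex(alpha) - sort_complex(Conj(alpha)))) < 1e-9
  if (is_real) v <- complex(real = Re(v), imaginary = 0)
  new_kernel(
    family = "espline", alpha = alpha, P = P, step = step,
    shift = 0, scale = 1 + 0i,
    t_lo = 0, t_hi = P + 1,
    grid_v = v
  )
}

sort_complex <- function(z) z[order(Re(z), Im(z))]

#' Construct a (truncated) Gaussian sampling kernel
#'
#' The normalized Gaussian \eqn{\varphi(t) = e^{-t^2/2\sigma^2} /
#' \sqrt{2\pi\sigma^2}} with Fourier transform
#' \eqn{\hat\varphi(\omega) = e^{-\omega^2\sigma^2/2}}.  It does not satisfy
#' the generalised Strang-Fix conditions, but its spectral leakage is tiny and
#' approximate exponential reproduction via [approx_coeffs()] is accurate.
#' The support is clipped where the amplitude falls below `trunc_tol`.
#'
#' @param sigma positive width parameter (normalized-time units).
#' @param trunc_tol truncation tolerance for the compact support.
#' @param step internal evaluation grid step (used only by quadrature code).
#' @return An object of class `fri_kernel`.
#' @export
make_gaussian <- function(sigma, trunc_tol = 1e-12, step = espline_step_default) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  tc <- sigma * sqrt(-2 * log(trunc_tol * sqrt(2 * pi * sigma^2)))
  tc <- ceiling(tc / step) * step
  new_kernel(
    family = "gaussian", sigma = sigma, P = NA_integer_, step = step,
    shift = 0, scale = 1 + 0i,
    t_lo = -tc, t_hi = tc,
    grid_v = NULL
  )
}

#' Effective kernel for the decaying-exponential finite-difference path
#'
#' Sampling a stream of decaying exponentials with kernel `phi` and computing
#' the finite differences \eqn{z_n = y_n - y_{n-1} e^{-\alpha T}} telescopes
#' the exponential tails away: `z` equals the samples of the underlying Dirac
#' stream taken with the compact-support kernel
#' \deqn{\psi(t) = T \int_0^1 e^{-\alpha T w}\, \varphi(t + w)\, \mathrm{d}w
#'   = T\, \beta_{-\alpha T}(-t) * \varphi(t),}
#' the convolution of `phi` with a time-reversed zero-order E-spline of
#' exponent \eqn{-\alpha T} (one extra exponent, shifted left by one sample
#' and rescaled).  Since convolution preserves exponential reproduction,
#' \eqn{\psi} reproduces the same exponentials as `phi`.
#'
#' With instantaneous sampling (`kernel = NULL`), as for a fluorescence trace
#' read directly off a two-photon microscope where \eqn{y_n = c(nT)}, the
#' factor `T` from the inner-product convention is dropped:
#' \eqn{\psi(t) = e^{\alpha T t} 1_{[-1, 0)}(t)}.
#'
#' @param kernel an E-spline `fri_kernel`, or `NULL` for instantaneous
#'   sampling.
#' @param alpha decay rate of the exponential pulses (1/seconds).
#' @param T sampling period (seconds).
#' @return An `fri_kernel` for \eqn{\psi}.
#' @export
effective_kernel <- function(kernel, alpha, T) {
  if (alpha <= 0 || T <= 0) stop("alpha and T must be positive")
  aT <- alpha * T
  if (is.null(kernel)) {
    k <- make_espline(aT)
    scale0 <- 1            # y_n = c(nT): no inner-product T factor
  } else {
    if (!inherits(kernel, "fri_kernel") || kernel$family != "espline") {
      stop("effective_kernel() supports E-spline kernels (or NULL for instantaneous sampling)")
    }
    k <- make_espline(c(kernel$alpha, aT), step = kernel$step)
    k$shift <- kernel$shift
    k$scale <- kernel$scale
    scale0 <- T
  }
  # psi(t) = scale0 * e^{-aT} * (phi * beta_{aT})(t + 1)
  k$shift <- k$shift - 1
  k$scale <- k$scale * scale0 * exp(-aT)
  k$t_lo <- k$t_lo - 1
  k$t_hi <- k$t_hi - 1
  k
}

#' Evaluate a sampling kernel pointwise
#'
#' @param kernel an `fri_kernel`.
#' @param t numeric vector of normalized-time points.
#' @return Numeric (or complex, for non-symmetric exponent sets) values; zero
#'   outside the support.
#' @export
kernel_eval <- function(kernel, t) {
  stopifnot(inherits(kernel, "fri_kernel"))
  tb <- t - kernel$shift   # base-kernel coordinates, support [0, L) / [-tc, tc)
  if (kernel$family == "gaussian") {
    v <- ifelse(tb >= kernel$t_lo & tb < kernel$t_hi,
      exp(-tb^2 / (2 * kernel$sigma^2)) / sqrt(2 * pi * kernel$sigma^2), 0)
    return(drop_tiny_imag(kernel$scale * v))
  }
  P <- kernel$P
  v <- if (P == 0L) {
    espline0_eval(kernel$alpha[1L], tb)
  } else if (P == 1L) {
    espline1_eval(kernel$alpha[1L], kernel$alpha[2L], tb)
  } else {
    interp_nodes(kernel$grid_v, 0, kernel$step, tb)
  }
  drop_tiny_imag(kernel$scale * v, tol = 1e-7)
}

#' Analytic Fourier transform of a sampling kernel
#'
#' For E-splines the product formula
#' \eqn{\hat\varphi(\omega) = \prod_m (1 - e^{\alpha_m - i\omega}) /
#' (i\omega - \alpha_m)}, with the removable singularity at
#' \eqn{i\omega = \alpha_m} evaluated by series expansion; for the Gaussian
#' the closed form \eqn{e^{-\omega^2\sigma^2/2}}.
#'
#' @param kernel an `fri_kernel`.
#' @param omega numeric vector of angular frequencies.
#' @return Complex values of \eqn{\hat\varphi(\omega)}.
#' @export
kernel_fourier <- function(kernel, omega) {
  stopifnot(inherits(kernel, "fri_kernel"))
  base <- if (kernel$family == "gaussian") {
    exp(-omega^2 * kernel$sigma^2 / 2) + 0i
  } else {
    out <- rep(1 + 0i, length(omega))
    for (a in kernel$alpha) {
      z <- 1i * omega - a
      small <- abs(z) < 1e-6
      f <- complex(length.out = length(z))
      f[!small] <- (1 - exp(-z[!small])) / z[!small]
      zs <- z[small]
      f[small] <- 1 - zs / 2 + zs^2 / 6 - zs^3 / 24
      out <- out * f
    }
    out
  }
  kernel$scale * exp(-1i * omega * kernel$shift) * base
}

#' Check the generalised Strang-Fix conditions on a frequency grid
#'
#' Exact exponential reproduction at frequencies \eqn{\omega_m} requires
#' \eqn{\hat\varphi(\omega_m) \neq 0} and
#' \eqn{\hat\varphi(\omega_m + 2\pi l) = 0} for every nonzero integer `l`.
#' E-splines built on the grid satisfy these by construction; other kernels
#' (e.g. the Gaussian) fail the second condition but may come numerically
#' close.
#'
#' @param kernel an `fri_kernel`.
#' @param grid an [frequency_grid()].
#' @param l_max largest |l| checked.
#' @param tol magnitude threshold distinguishing "zero" from "nonzero".
#' @return A data frame with one row per frequency: `omega`, `mag_ongrid`
#'   (\eqn{|\hat\varphi(\omega_m)|}), `max_offgrid_magnitude` and the logical
#'   `passes_exact`.
#' @export
verify_strang_fix <- function(kernel, grid, l_max = 10L, tol = 1e-9) {
  stopifnot(inherits(grid, "fri_grid"))
  if (l_max < 1L) stop("l_max must be >= 1")
  ls <- setdiff(-l_max:l_max, 0L)
  res <- lapply(grid$omegas, function(w) {
    on <- abs(kernel_fourier(kernel, w))
    off <- max(abs(kernel_fourier(kernel, w + 2 * pi * ls)))
    data.frame(omega = w, mag_ongrid = on, max_offgrid_magnitude = off,
               passes_exact = on > tol && off < tol)
  })
  do.call(rbind, res)
}

new_coeff_table <- function(c_mat, grid, n0, mode) {
  structure(c_mat, grid = grid, n0 = n0, mode = mode, class = "fri_coeffs")
}

#' Exact exponential-reproduction coefficients
#'
#' For a kernel satisfying the generalised Strang-Fix conditions on `grid`,
#' the coefficients \eqn{c_{m,n} = e^{i\omega_m n} c_{m,0}} with
#' \eqn{c_{m,0} = 1/\hat\varphi(\omega_m)} make
#' \eqn{\sum_n c_{m,n}\varphi(t-n) = e^{i\omega_m t}} exactly.  When the sum
#' is truncated to `n` in `n_range`, perfect reproduction holds on the
#' interior interval `[n0 - 1 + t_hi, nf + 1 + t_lo)` where `[t_lo, t_hi)` is
#' the kernel support.
#'
#' @param kernel an `fri_kernel` satisfying Strang-Fix on `grid`.
#' @param grid an [frequency_grid()].
#' @param n_range integer vector (only its range is used) of shifts `n`.
#' @param tol tolerance for the Strang-Fix check / degenerate-kernel test.
#' @param check if `TRUE` (default) verify the Strang-Fix conditions first.
#' @return A complex matrix of class `fri_coeffs`, rows `m = 0..P`, columns
#'   the requested `n`, with attributes `grid`, `n0` and `mode = "exact"`.
#' @export
reproduction_coeffs <- function(kernel, grid, n_range, tol = 1e-9, check = TRUE) {
  ns <- seq.int(min(n_range), max(n_range))
  phat <- kernel_fourier(kernel, grid$omegas)
  if (any(abs(phat) <= tol)) {
    stop("degenerate kernel: |phi_hat(omega_m)| vanishes on the grid")
  }
  if (check) {
    sf <- verify_strang_fix(kernel, grid, tol = tol)
    if (!all(sf$passes_exact)) {
      stop("kernel does not satisfy the Strang-Fix conditions on this grid; ",
           "use approx_coeffs() for approximate reproduction")
    }
  }
  c0 <- 1 / phat
  cmat <- outer(seq_along(grid$omegas), seq_along(ns),
                function(m, j) c0[m] * exp(1i * grid$omegas[m] * ns[j]))
  new_coeff_table(cmat, grid, ns[1L], "exact")
}

#' Constant least-squares (approximate) reproduction coefficients
#'
#' For kernels that do not satisfy the Strang-Fix conditions the exponentials
#' can still be reproduced approximately.  The constant least-squares choice
#' keeps the pure-phase structure \eqn{c_{m,n} = e^{i\omega_m n} c_{m,0}} and
#' picks the constant minimizing the L2 reproduction error,
#' \deqn{c_{m,0} = \hat\varphi(\omega_m)^* \Big/ \sum_l
#'   |\hat\varphi(\omega_m + 2\pi l)|^2,}
#' which reduces to the exact \eqn{1/\hat\varphi(\omega_m)} when the off-grid
#' spectrum vanishes.
#'
#' @inheritParams reproduction_coeffs
#' @param l_sum number of spectral replicas summed in the normalization.
#' @return An `fri_coeffs` matrix with `mode = "constant_least_squares"`.
#' @export
approx_coeffs <- function(kernel, grid, n_range, tol = 1e-9, l_sum = 200L) {
  ns <- seq.int(min(n_range), max(n_range))
  phat <- kernel_fourier(kernel, grid$omegas)
  if (any(abs(phat) <= tol)) {
    stop("degenerate kernel: |phi_hat(omega_m)| vanishes on the grid")
  }
  ls <- -l_sum:l_sum
  c0 <- vapply(grid$omegas, function(w) {
    Conj(kernel_fourier(kernel, w)) /
      sum(abs(kernel_fourier(kernel, w + 2 * pi * ls))^2)
  }, complex(1))
  cmat <- outer(seq_along(grid$omegas), seq_along(ns),
                function(m, j) c0[m] * exp(1i * grid$omegas[m] * ns[j]))
  new_coeff_table(cmat, grid, ns[1L], "constant_least_squares")
}

#' Evaluate a truncated reproduction sum
#'
#' Computes \eqn{\sum_n c_{m,n} \varphi(t - n)} for one row `m` of a
#' coefficient table, for checking reproduction accuracy against
#' \eqn{e^{i\omega_m t}}.
#'
#' @param kernel the kernel the coefficients were computed for.
#' @param coeffs an `fri_coeffs` table.
#' @param m frequency index (0-based, `0..P`).
#' @param t evaluation points.
#' @return Complex values of the truncated sum.
#' @export
reproduction_sum <- function(kernel, coeffs, m, t) {
  ns <- attr(coeffs, "n0") + seq_len(ncol(coeffs)) - 1L
  out <- complex(length.out = length(t))
  for (j in seq_along(ns)) {
    out <- out + coeffs[m + 1L, j] * kernel_eval(kernel, t - ns[j])
  }
  out
}

#' Interior interval of exact truncated reproduction
#'
#' @param kernel an `fri_kernel`.
#' @param coeffs an `fri_coeffs` table (for its shift range).
#' @return Numeric `c(lo, hi)`: the half-open interval on which the truncated
#'   reproduction sum is free of border effects.
#' @export
reproduction_interior <- function(kernel, coeffs) {
  n0 <- attr(coeffs, "n0")
  nf <- n0 + ncol(coeffs) - 1L
  c(n0 - 1 + kernel$t_hi, nf + 1 + kernel$t_lo)
}

#' @export
print.fri_kernel <- function(x, ...) {
  if (x$family == "espline") {
    cat(sprintf("<fri_kernel> E-spline, order P = %d, support [%g, %g)\n",
                x$P, x$t_lo + 0, x$t_hi))
  } else {
    cat(sprintf("<fri_kernel> Gaussian, sigma = %g, truncated support [%g, %g)\n",
                x$sigma, x$t_lo, x$t_hi))
  }
  invisible(x)
}

#' @export
plot.fri_kernel <- function(x, n = 512L, ...) {
  tt <- seq(x$t_lo + x$shift, x$t_hi + x$shift, length.out = n)
  graphics::plot(tt, Re(kernel_eval(x, tt)), type = "l",
                 xlab = "t (normalized time)", ylab = expression(varphi(t)), ...)
  invisible(x)
}
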