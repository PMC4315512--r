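# Fourier-domain moments and annihilating-filter (Prony) recovery.
#
# Linearly combining the samples with exponential-reproduction coefficients
# yields s_m = sum_n c_{m,n} y_n = xhat(-omega_m / T): a uniform slice of the
# Fourier transform of the input.  For a stream of K Diracs,
# s_m = sum_k b_k u_k^m with b_k = a_k e^{i omega_0 t_k / T} and
# u_k = e^{i lambda t_k / T}; the u_k are the roots of the annihilating
# filter, recovered from a Toeplitz linear system.

#' Moment vector
#'
#' @param s complex vector `s_m`, `m = 0..P`.
#' @param grid the [frequency_grid()] the moments live on.
#' @param T sampling period in seconds.
#' @return An object of class `fri_moments`.
#' @export
fri_moments <- function(s, grid, T = 1) {
  stopifnot(inherits(grid, "fri_grid"))
  if (length(s) != grid$P + 1L) stop("length(s) must equal P + 1")
  structure(list(s = as.complex(s), grid = grid, T = T), class = "fri_moments")
}

moment_values <- function(s) if (inherits(s, "fri_moments")) s$s else as.complex(s)

#' Compute Fourier-domain moments from samples
#'
#' \eqn{s_m = \sum_n c_{m,n} y_n}.  With exact-mode coefficients and noiseless
#' samples of a Dirac stream this equals \eqn{\hat x(-\omega_m / T)} to
#' numerical accuracy.
#'
#' @param samples a [sample_sequence()].
#' @param coeffs an `fri_coeffs` table whose shift range covers the sample
#'   index range.
#' @return An [fri_moments()] object.
#' @export
compute_moments <- function(samples, coeffs) {
  stopifnot(inherits(samples, "sample_seq"), inherits(coeffs, "fri_coeffs"))
  n0 <- attr(coeffs, "n0")
  nf <- n0 + ncol(coeffs) - 1L
  ns <- sample_indices(samples)
  if (min(ns) < n0 || max(ns) > nf) {
    stop(sprintf("coefficient index range [%d, %d] does not cover sample range [%d, %d]",
                 n0, nf, min(ns), max(ns)))
  }
  cols <- ns - n0 + 1L
  s <- drop(coeffs[, cols, drop = FALSE] %*% samples$values)
  fri_moments(s, attr(coeffs, "grid"), samples$T)
}

#' Finite differences reducing an exponential stream to a Dirac stream
#'
#' \eqn{z_n = y_n - y_{n-1} e^{-\alpha T}}.  For samples of a stream of
#' decaying exponentials this telescopes the tails away: `z` equals the
#' samples of the underlying Dirac stream taken with the effective kernel
#' \eqn{\psi(t) = \beta_{\alpha T}(-t) * \varphi(t)} (see
#' [effective_kernel()]), and has finitely many nonzero entries.  The sample
#' preceding the first stored one is taken as zero.
#'
#' @param samples a [sample_sequence()] with contiguous indices.
#' @param alpha decay rate in 1/seconds.
#' @return A [sample_sequence()] of the same length and indexing.
#' @export
finite_difference <- function(samples, alpha) {
  stopifnot(inherits(samples, "sample_seq"))
  y <- samples$values
  z <- y - c(0, y[-length(y)]) * exp(-alpha * samples$T)
  sample_sequence(z, T = samples$T, n_start = samples$n_start,
                  noise_sigma = samples$noise_sigma)
}

#' Reproduction coefficients for the effective kernel of the
#' finite-difference path
#'
#' The effective kernel \eqn{\psi(t) = \beta_{\alpha T}(-t) * \varphi(t)}
#' reproduces the same exponentials as \eqn{\varphi}; its Fourier transform is
#' the analytic product \eqn{\hat\psi(\omega) = \hat\beta_{\alpha T}(-\omega)
#' \hat\varphi(\omega)}, so the coefficients `d_{m,n}` follow from the same
#' formulas as [reproduction_coeffs()] / [approx_coeffs()].
#'
#' @inheritParams reproduction_coeffs
#' @param kernel the acquisition kernel \eqn{\varphi}, or `NULL` for
#'   instantaneous sampling.
#' @param alpha decay rate (1/seconds).
#' @param T sampling period (seconds).
#' @param mode `"exact"` (Strang-Fix kernels) or `"cls"` (constant
#'   least-squares, required for instantaneous sampling).
#' @return An `fri_coeffs` table for \eqn{\psi}.
#' @export
effective_coeffs <- function(kernel, alpha, T, grid, n_range,
                             mode = c("exact", "cls"), tol = 1e-9) {
  mode <- match.arg(mode)
  psi <- effective_kernel(kernel, alpha, T)
  if (mode == "exact") {
    reproduction_coeffs(psi, grid, n_range, tol = tol)
  } else {
    approx_coeffs(psi, grid, n_range, tol = tol)
  }
}

#' Annihilating-filter (Prony) solution
#'
#' Solves the linear recurrence \eqn{h_K s_{m-K} + \cdots + h_1 s_{m-1} + s_m
#' = 0} for the filter coefficients using all available rows (least squares
#' when overdetermined), extracts the roots \eqn{u_k} of
#' \eqn{z^K + h_1 z^{K-1} + \cdots + h_K} from the companion matrix, and fits
#' the weights \eqn{b_k} of \eqn{s_m = \sum_k b_k u_k^m} by least squares.
#'
#' @param s an [fri_moments()] object or complex vector of moments.
#' @param K number of events; requires `length(s) >= 2 K`.
#' @return A list of class `prony_fit` with `u`, `b`, `h` (the `K` filter
#'   coefficients), `residual` (RMS moment fit error) and `diagnostics`
#'   (Toeplitz singular values and a degeneracy flag).
#' @export
prony <- function(s, K) {
  sv <- moment_values(s)
  P <- length(sv) - 1L
  if (K < 1L) stop("K must be >= 1")
  if (P + 1L < 2L * K) {
    stop(sprintf("insufficient moments: recovering K = %d events needs P + 1 >= 2K = %d, got %d",
                 K, 2L * K, P + 1L))
  }
  A <- outer(seq_len(P + 1L - K), seq_len(K),
             function(r, j) sv[K + r - j])
  rhs <- -sv[(K + 1L):(P + 1L)]
  dA <- svd(A)$d
  degenerate <- K > 1L && dA[K] < max(dA) * 1e-10
  if (degenerate) {
    warning("Toeplitz system numerically rank deficient; event configuration may be degenerate")
  }
  h <- cls_solve(A, rhs)
  u <- if (K == 1L) -h else {
    comp <- rbind(-h, cbind(diag(1 + 0i, K - 1L), complex(length.out = K - 1L)))
    eigen(comp, only.values = TRUE)$values
  }
  V <- outer(0:P, seq_len(K), function(m, k) u[k]^m)
  b <- cls_solve(V, sv)
  res <- sqrt(mean(Mod(drop(V %*% b) - sv)^2))
  structure(list(u = u, b = b, h = h, residual = res,
                 diagnostics = list(singular_values = dA,
                                    degenerate = degenerate)),
            class = "prony_fit")
}

#' Map a Prony solution to event times and amplitudes
#'
#' Inverts \eqn{u_k = e^{i\lambda t_k/T}} and
#' \eqn{b_k = a_k e^{i\omega_0 t_k/T}}: \eqn{t_k = T\,\mathrm{arg}(u_k)/\lambda}
#' with the argument taken in \eqn{[0, 2\pi)} (times are unambiguous within
#' `N` sampling periods when `lambda = 2*pi/N`), and
#' \eqn{a_k = b_k e^{-i\omega_0 t_k / T}}.
#'
#' @param sol a `prony_fit` (or any list with `u`, `b`).
#' @param grid the [frequency_grid()] used for the moments.
#' @param T sampling period in seconds.
#' @param unit_tol moduli `|u_k|` further than this from 1 are flagged in the
#'   diagnostics (a noise/border indicator), not an error.
#' @return A list of class `fri_recon` with `events` (data frame `t`, `a`
#'   sorted by `t`), `K` and `diagnostics` (`u_moduli`, `off_circle`,
#'   `residual`).
#' @export
solution_to_events <- function(sol, grid, T, unit_tol = 0.2) {
  stopifnot(inherits(grid, "fri_grid"))
  if (grid$lambda == 0) stop("lambda must be nonzero")
  u <- sol$u
  theta <- Arg(u)
  theta[theta < 0] <- theta[theta < 0] + 2 * pi
  tk <- T * theta / grid$lambda
  ak <- sol$b * exp(-1i * grid$omega0 * tk / T)
  ord <- order(tk)
  events <- data.frame(t = tk[ord], a = Re(ak[ord]))
  structure(list(
    events = events, K = length(u),
    diagnostics = list(
      u_moduli = Mod(u)[ord],
      off_circle = abs(Mod(u)[ord] - 1) > unit_tol,
      a_imag_max = max(abs(Im(ak))),
      residual = sol$residual %||% NA_real_
    )
  ), class = "fri_recon")
}

#' @export
print.fri_recon <- function(x, ...) {
  cat(sprintf("<fri_recon> K = %d events\n", x$K))
  print(x$events, ...)
  invisible(x)
}

#' Toeplitz moment matrix
#'
#' The \eqn{(\lfloor P/2\rfloor + 1) \times (\lceil P/2\rceil + 1)} Toeplitz
#' matrix with entries \eqn{S_{ij} = s_{\lceil P/2\rceil + i - j}}.  In the
#' noiseless case its rank equals the number of events `K`.
#'
#' @param s moments (vector or [fri_moments()]).
#' @return A complex matrix.
#' @export
moment_matrix <- function(s) {
  sv <- moment_values(s)
  P <- length(sv) - 1L
  cP <- ceiling(P / 2)
  outer(seq_len(floor(P / 2) + 1L), seq_len(cP + 1L),
        function(i, j) sv[cP + i - j + 1L])
}

# inverse of moment_matrix: average the (constant) diagonals back to s_0..s_P
moment_matrix_to_s <- function(S, P) {
  cP <- ceiling(P / 2)
  m_of <- outer(seq_len(nrow(S)), seq_len(ncol(S)), function(i, j) cP + i - j)
  vapply(0:P, function(m) mean(S[m_of == m]), complex(1))
}

#' Estimate the number of events from the moment singular values
#'
#' Counts the singular values of the Toeplitz moment matrix whose ratio to the
#' largest one is at least `mu0`.  With noise the matrix is full rank and the
#' threshold trades off misses against false events; the estimator never
#' returns 0 (the largest normalized singular value is always 1) and tends to
#' overestimate in noise.
#'
#' @param s moments (vector or [fri_moments()]), length at least 2.
#' @param mu0 relative singular-value threshold in (0, 1).
#' @return Integer estimate of `K` (at least 1).
#' @export
estimate_K <- function(s, mu0 = 0.3) {
  sv <- moment_values(s)
  if (length(sv) < 2L) stop("need at least two moments")
  if (mu0 <= 0 || mu0 >= 1) stop("mu0 must be in (0, 1)")
  d <- svd(moment_matrix(sv))$d
  max(1L, sum(d / d[1L] >= mu0))
}

#' One-shot reconstruction of a localized FRI signal
#'
#' Convenience wrapper running the full pipeline on one block of samples:
#' (optional) finite differences for decaying-exponential inputs, moment
#' computation, (optional) Cadzow denoising, annihilating filter
#' (least-squares Prony or total least squares) or matrix pencil, and the
#' mapping back to `(t_k, a_k)`.
#'
#' @param samples a [sample_sequence()].
#' @param kernel the acquisition kernel (`NULL` with `alpha` set means
#'   instantaneous sampling of an exponential stream).
#' @param grid a [frequency_grid()].
#' @param K number of events, or `NULL` to use [estimate_K()].
#' @param alpha decay rate for the exponential-stream path, or `NULL` for
#'   Dirac inputs.
#' @param denoise `"none"` or `"cadzow"`.
#' @param method root estimation: `"tls"`, `"prony"`, or `"pencil"`.
#' @param coeff_mode `"exact"` or `"cls"` reproduction coefficients.
#' @param mu0 threshold for [estimate_K()] when `K` is `NULL`.
#' @param project_unit project the roots onto the unit circle before the
#'   amplitude fit (off by default: raw Prony matches the noiseless theory;
#'   projection can help with noisy data).
#' @return An `fri_recon` (see [solution_to_events()]).
#' @export
reconstruct <- function(samples, kernel, grid, K = NULL, alpha = NULL,
                        denoise = c("none", "cadzow"),
                        method = c("tls", "prony", "pencil"),
                        coeff_mode = c("exact", "cls"), mu0 = 0.3,
                        project_unit = FALSE) {
  denoise <- match.arg(denoise)
  method <- match.arg(method)
  coeff_mode <- match.arg(coeff_mode)
  ns <- sample_indices(samples)
  nr <- range(ns)
  if (!is.null(alpha)) {
    samples <- finite_difference(samples, alpha)
    co <- effective_coeffs(kernel, alpha, samples$T, grid, nr,
                           mode = if (coeff_mode == "exact") "exact" else "cls")
  } else {
    co <- if (coeff_mode == "exact") {
      reproduction_coeffs(kernel, grid, nr)
    } else {
      approx_coeffs(kernel, grid, nr)
    }
  }
  s <- compute_moments(samples, co)
  if (is.null(K)) K <- min(estimate_K(s, mu0), floor((grid$P + 1) / 2))
  if (denoise == "cadzow") s <- cadzow(s, K)
  refit <- function(u) {
    if (project_unit) u <- u / Mod(u)
    V <- outer(0:grid$P, seq_len(K), function(m, k) u[k]^m)
    b <- cls_solve(V, moment_values(s))
    list(u = u, b = b,
         residual = sqrt(mean(Mod(drop(V %*% b) - moment_values(s))^2)))
  }
  sol <- switch(method,
    prony = if (project_unit) refit(prony(s, K)$u) else prony(s, K),
    tls = {
      h <- tls_annihilator(s, K)
      u <- if (K == 1L) -h[2L] else {
        comp <- rbind(-h[-1L], cbind(diag(1 + 0i, K - 1L), complex(length.out = K - 1L)))
        eigen(comp, only.values = TRUE)$values
      }
      refit(u)
    },
    pencil = refit(matrix_pencil(s, K))
  )
  solution_to_events(sol, grid, samples$T)
}
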