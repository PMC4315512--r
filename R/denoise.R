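# Noise-robust moment processing: Cadzow alternating projections, the total
# least-squares annihilating filter, and matrix-pencil root estimation.

#' Cadzow iterative denoising
#'
#' Alternates two projections on the Toeplitz moment matrix: (i) the best
#' rank-`K` approximation (keep the `K` largest singular values), and (ii) the
#' nearest Toeplitz matrix (average each diagonal).  Stops when
#' \eqn{\mu_{K+1}/\mu_1 < tol} or after `max_iter` sweeps, and reads the
#' cleaned moments off the final matrix.  Noiseless rank-`K` moments are a
#' fixed point.
#'
#' @param s moments (vector or [fri_moments()]).
#' @param K target rank (number of events); must be less than the smaller
#'   matrix dimension.
#' @param max_iter maximum number of sweeps.
#' @param tol stopping threshold on the normalized `(K+1)`-th singular value.
#' @return Denoised moments, same type as the input.
#' @export
cadzow <- function(s, K, max_iter = 20L, tol = 1e-10) {
  sv <- moment_values(s)
  P <- length(sv) - 1L
  S <- moment_matrix(sv)
  if (K >= min(dim(S))) {
    stop(sprintf("K = %d must be smaller than the Toeplitz matrix dimension %d",
                 K, min(dim(S))))
  }
  out <- sv
  for (it in seq_len(max_iter)) {
    S <- moment_matrix(out)
    dec <- svd(S)
    if (dec$d[K + 1L] / dec$d[1L] < tol) break
    Sk <- dec$u[, seq_len(K), drop = FALSE] %*%
      (dec$d[seq_len(K)] * Conj(t(dec$v[, seq_len(K), drop = FALSE])))
    out <- moment_matrix_to_s(Sk, P)
  }
  if (inherits(s, "fri_moments")) fri_moments(out, s$grid, s$T) else out
}

#' Total least-squares annihilating filter
#'
#' Minimizes \eqn{\|S h\|^2} subject to \eqn{\|h\| = 1} over filters of
#' length `K + 1`, where `S` is the Toeplitz matrix of the moments with
#' `K + 1` columns; the solution is the right singular vector of the smallest
#' singular value, normalized so its first element is 1 (its trailing `K`
#' entries are then the recurrence coefficients `h_1..h_K`).
#'
#' @param s moments (vector or [fri_moments()]).
#' @param K number of events.
#' @return Complex vector `h` of length `K + 1` with `h[1] == 1`.
#' @export
tls_annihilator <- function(s, K) {
  sv <- moment_values(s)
  P <- length(sv) - 1L
  if (P + 1L < 2L * K) {
    stop(sprintf("insufficient moments: need P + 1 >= 2K, got %d < %d",
                 P + 1L, 2L * K))
  }
  A <- outer(seq_len(P + 1L - K), seq_len(K + 1L),
             function(i, j) sv[K + i - j + 1L])
  dec <- svd(A, nu = 0, nv = ncol(A))   # full right vectors: the annihilator
  h <- dec$v[, ncol(A)]                 # may live in the nullspace of a wide A
  if (Mod(h[1L]) < 1e-12 * max(Mod(h))) {
    stop("TLS normalization failure: leading annihilator coefficient is zero")
  }
  h / h[1L]
}

#' Matrix-pencil estimation of the unit-circle parameters
#'
#' Builds the Toeplitz moment matrix `S`, restricts it to its `K`-dimensional
#' signal subspace (the `K` leading left singular vectors), and solves the
#' shifted/unshifted pencil: the parameters `u_k` are the rank-reducing
#' numbers of the pencil formed by `S` with its first (respectively last) row
#' dropped.
#'
#' @param s moments (vector or [fri_moments()]).
#' @param K number of events; the matrix must have at least `K + 1` rows.
#' @return Complex vector of `K` estimates `u_k`.
#' @export
matrix_pencil <- function(s, K) {
  sv <- moment_values(s)
  S <- moment_matrix(sv)
  if (nrow(S) < K + 1L) {
    stop(sprintf("degenerate pencil: moment matrix has %d rows, need at least K + 1 = %d",
                 nrow(S), K + 1L))
  }
  dec <- svd(S)
  U <- dec$u[, seq_len(K), drop = FALSE]
  U0 <- U[-1L, , drop = FALSE]          # rows 2..R: shifted up by one power
  U1 <- U[-nrow(U), , drop = FALSE]     # rows 1..R-1
  d1 <- svd(U1)$d
  if (d1[K] < max(d1) * 1e-10) {
    stop("degenerate pencil: signal subspace is rank deficient")
  }
  M <- cls_solve_mat(U1, U0)
  eigen(M, only.values = TRUE)$values
}

# least-squares solve with a matrix right-hand side
cls_solve_mat <- function(A, B) {
  sv <- svd(A)
  keep <- sv$d > max(sv$d) * 1e-12
  r <- sum(keep)
  sv$v[, seq_len(r), drop = FALSE] %*%
    ((Conj(t(sv$u[, seq_len(r), drop = FALSE])) %*% B) / sv$d[seq_len(r)])
}
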