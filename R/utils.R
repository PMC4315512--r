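#' frispike: finite-rate-of-innovation sampling and spike inference
#'
#' Tools for sampling and reconstructing streams of Diracs and decaying
#' exponentials with exponential-reproducing kernels, and for inferring
#' spike trains from two-photon calcium fluorescence traces via a
#' sliding-window, double-consistency search.
#'
#' @keywords internal
"_PACKAGE"

# Internal numerical helpers shared across modules.

# Cumulative integral of f sampled at uniform step h, returned at every node.
# Composite Simpson at even node counts, an asymmetric three-point rule at odd
# ones; O(h^4) for integrands smooth between nodes.
cumsimp <- function(f, h) {
  n <- length(f)
  g <- complex(length.out = n)
  if (n < 2L) return(g)
  if (n == 2L) {
    g[2L] <- h / 2 * (f[1L] + f[2L])
    return(g)
  }
  odd <- seq(3L, n, by = 2L)
  g[odd] <- cumsum(h / 3 * (f[odd - 2L] + 4 * f[odd - 1L] + f[odd]))
  even <- seq(2L, n, by = 2L)
  ev <- even[even < n]
  g[ev] <- g[ev - 1L] + h / 12 * (5 * f[ev - 1L] + 8 * f[ev] - f[ev + 1L])
  if (n %% 2L == 0L) {
    # trailing interval: quadratic through the last three nodes
    g[n] <- g[n - 1L] + h / 12 * (-f[n - 2L] + 8 * f[n - 1L] + 5 * f[n])
  }
  g
}

# Minimum-norm least-squares solution of A x = b for complex A, via SVD.
cls_solve <- function(A, b, rcond = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > max(sv$d) * rcond
  r <- sum(keep)
  if (r == 0L) stop("cls_solve(): numerically zero system matrix")
  drop(sv$v[, seq_len(r), drop = FALSE] %*%
    ((Conj(t(sv$u[, seq_len(r), drop = FALSE])) %*% b) / sv$d[seq_len(r)]))
}

# Evaluate a complex-valued function tabulated at nodes x0 + (0:(n-1))*h by
# 4-point Lagrange interpolation; zero outside [x0, x0 + (n-1)*h).
interp_nodes <- function(v, x0, h, x) {
  out <- complex(length.out = length(x))
  n <- length(v)
  u <- (x - x0) / h
  idx <- which(u >= 0 & u < n - 1L)
  if (!length(idx)) return(out)
  ui <- u[idx]
  j0 <- pmax(0, pmin(floor(ui) - 1, n - 4L))
  s <- ui - j0
  y0 <- v[j0 + 1L]; y1 <- v[j0 + 2L]; y2 <- v[j0 + 3L]; y3 <- v[j0 + 4L]
  out[idx] <- y0 * (-(s - 1) * (s - 2) * (s - 3) / 6) +
    y1 * (s * (s - 2) * (s - 3) / 2) +
    y2 * (-s * (s - 1) * (s - 3) / 2) +
    y3 * (s * (s - 1) * (s - 2) / 6)
  out
}

# Run expr with a temporary RNG state seeded from `seed` (NULL = leave RNG
# alone), restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

drop_tiny_imag <- function(x, tol = 1e-8) {
  if (max(abs(Im(x))) < tol * max(1, max(abs(x)))) Re(x) else x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
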