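# Moments, the annihilating filter, the finite-difference reduction, and
# model-order estimation.

Tper <- 1 / 16

test_that("moments of a Dirac stream equal the Fourier transform at the grid", {
  st <- dirac_stream(c(0.2, 0.5, 0.9, 1.3), c(1, 2, 0.5, 1.5))
  y <- sample_diracs(st, crit_kernel, Tper)
  nr <- c(y$n_start, y$n_start + length(y$values) - 1L)
  co <- reproduction_coeffs(crit_kernel, crit_grid, nr)
  s <- compute_moments(y, co)
  tau <- st$times / Tper
  s_true <- vapply(crit_grid$omegas,
                   function(w) sum(st$amplitudes * exp(1i * w * tau)),
                   complex(1))
  expect_lt(max(abs(s$s - s_true)) / max(abs(s_true)), 1e-6)

  # |s_m| = a for a single Dirac; conjugate symmetry for real inputs
  y1 <- sample_diracs(dirac_stream(0.37, 1.7), crit_kernel, Tper)
  co1 <- reproduction_coeffs(crit_kernel, crit_grid,
                             c(y1$n_start, y1$n_start + length(y1$values) - 1L))
  s1 <- compute_moments(y1, co1)
  expect_equal(Mod(s1$s), rep(1.7, 8), tolerance = 1e-8)
  expect_lt(max(abs(s1$s - Conj(rev(s1$s)))), 1e-8)

  # all-zero samples give all-zero moments
  z <- sample_sequence(rep(0, 20), Tper, n_start = 0L)
  co0 <- reproduction_coeffs(crit_kernel, crit_grid, c(0, 19))
  expect_equal(compute_moments(z, co0)$s, rep(0 + 0i, 8))

  # coefficient range must cover the samples
  expect_error(compute_moments(sample_sequence(rep(1, 30), Tper, -5), co0),
               "does not cover")
})

test_that("prony recovers geometric sequences exactly", {
  # K = 1 closed form
  s <- 3 * exp(1i * 0.7)^(0:5)
  pf <- prony(s, 1)
  expect_equal(pf$h, -exp(1i * 0.7), tolerance = 1e-12)
  expect_equal(pf$u, exp(1i * 0.7), tolerance = 1e-12)
  expect_equal(pf$b, 3 + 0i, tolerance = 1e-12)

  # K = 2 forward synthesis oracle
  u <- exp(1i * c(0.4, 1.9))
  b <- c(1.5, -0.8 + 0.3i)
  s2 <- synth_moments(b, u, 7)
  pf2 <- prony(s2, 2)
  expect_lt(max(abs(sort_by_arg(pf2$u) - sort_by_arg(u))), 1e-10)
  expect_lt(pf2$residual, 1e-10)

  # scaling invariance: u unchanged, b scales
  pf3 <- prony(10 * s2, 2)
  expect_lt(max(abs(sort_by_arg(pf3$u) - sort_by_arg(pf2$u))), 1e-10)
  expect_equal(sum(pf3$b), 10 * sum(pf2$b), tolerance = 1e-9)

  expect_error(prony(s2, 5), "insufficient moments")
})

test_that("the noiseless Toeplitz moment matrix has numerical rank K", {
  for (K in 1:5) {
    P <- 11
    u <- exp(1i * 2 * pi * (seq_len(K) * 7 %% 23) / 23)
    b <- seq_len(K) + 0.5
    S <- moment_matrix(synth_moments(b, u, P))
    d <- svd(S)$d
    expect_gt(d[K] / d[1], 1e-9)
    if (K < length(d)) expect_lt(d[K + 1] / d[1], 1e-10)
  }
})

test_that("solution_to_events inverts the phase/amplitude encoding", {
  # u = 1, b = a -> t = 0, amplitude a
  g <- frequency_grid(3, N = 16)
  sol <- list(u = 1 + 0i, b = 2.5 + 0i)
  rec <- solution_to_events(sol, g, T = 0.1)
  expect_equal(rec$events$t, 0)
  expect_equal(rec$events$a, 2.5)

  # off-circle roots are flagged, not fatal
  sol2 <- list(u = 1.5 * exp(1i), b = 1 + 0i)
  rec2 <- solution_to_events(sol2, g, T = 0.1)
  expect_true(rec2$diagnostics$off_circle)
})

test_that("the noiseless pipeline satisfies the perfect-reconstruction theorem", {
  # random K <= floor((P+1)/2), random times/amplitudes, many trials
  set.seed(123)
  for (trial in 1:20) {
    K <- sample(1:4, 1)
    tk <- random_events(K, 1, 21, min_gap = 0.05, T = Tper)
    ak <- stats::runif(K, 0.5, 2) * sample(c(-1, 1), K, replace = TRUE)
    st <- dirac_stream(tk, ak)
    y <- sample_diracs(st, crit_kernel, Tper)
    rec <- reconstruct(y, crit_kernel, crit_grid, K = K, method = "prony")
    expect_events_equal(rec, tk, ak, tol_t = 1e-6, T = Tper, tol_a = 1e-5)
    expect_lt(rec$diagnostics$a_imag_max, 1e-6)
  }
})

test_that("finite differences telescope exponential tails to zero", {
  y <- sample_sequence(5 * exp(-2 * (0:30) * Tper), Tper)
  z <- finite_difference(y, 2)
  expect_equal(z$values[-1], rep(0, 30), tolerance = 1e-14)

  z0 <- finite_difference(sample_sequence(rep(0, 10), Tper), 2)
  expect_equal(z0$values, rep(0, 10))
})

test_that("finite differences equal Dirac sampling with the effective kernel", {
  alpha <- 2
  st <- dirac_stream(c(0.2, 0.5, 0.9, 1.3), c(1, 2, 0.5, 1.5))
  es <- exponential_stream(st$times, st$amplitudes, alpha = alpha)
  y <- sample_stream(es, crit_kernel, Tper)
  z <- finite_difference(y, alpha)
  psi <- effective_kernel(crit_kernel, alpha, Tper)
  nr <- c(y$n_start, y$n_start + length(y$values) - 1L)
  zd <- sample_diracs(st, psi, Tper, n_range = nr)
  expect_lt(max(abs(z$values - zd$values)), 1e-8)
  # finitely many nonzero entries
  expect_lt(sum(abs(z$values) > 1e-10), 5 * (crit_kernel$P + 2L))
})

test_that("effective coefficients recover the geometric moment model", {
  alpha <- 2
  # alpha = 0 limit check via the analytic product: psi_hat = box-factor * phi_hat
  psi <- effective_kernel(crit_kernel, alpha, Tper)
  w <- crit_grid$omegas[3]
  aT <- alpha * Tper
  # T * Fourier transform of the time-reversed zero-order factor
  box_fac <- Tper * (1 - exp(-aT + 1i * w)) / (aT - 1i * w)
  expect_equal(kernel_fourier(psi, w),
               box_fac * kernel_fourier(crit_kernel, w), tolerance = 1e-10)

  # interior reproduction of the effective kernel
  dco <- effective_coeffs(crit_kernel, alpha, Tper, crit_grid, c(0, 40))
  intv <- reproduction_interior(psi, dco)
  tt <- seq(intv[1], intv[2] - 0.01, length.out = 300)
  res <- reproduction_sum(psi, dco, 2, tt) - exp(1i * crit_grid$omegas[3] * tt)
  expect_lt(max(abs(res)), 1e-6)

  # end-to-end: z_n + d_{m,n} gives s_m = sum_k b_k u_k^m
  st <- dirac_stream(c(0.2, 0.5, 0.9, 1.3), c(1, 2, 0.5, 1.5))
  es <- exponential_stream(st$times, st$amplitudes, alpha = alpha)
  y <- sample_stream(es, crit_kernel, Tper)
  z <- finite_difference(y, alpha)
  nr <- c(z$n_start, z$n_start + length(z$values) - 1L)
  dco2 <- effective_coeffs(crit_kernel, alpha, Tper, crit_grid, nr)
  s <- compute_moments(z, dco2)
  tau <- st$times / Tper
  b <- st$amplitudes * exp(1i * crit_grid$omega0 * tau)
  u <- exp(1i * crit_grid$lambda * tau)
  expect_lt(max(abs(s$s - synth_moments(b, u, 7))) / max(abs(s$s)), 1e-6)
})

test_that("moment paths agree: finite-difference route vs direct Dirac route", {
  alpha <- 1.7
  st <- dirac_stream(c(0.31, 0.72, 1.13), c(1, -0.6, 1.4))
  es <- exponential_stream(st$times, abs(st$amplitudes), alpha = alpha)
  # direct Dirac route with kernel psi
  psi <- effective_kernel(crit_kernel, alpha, Tper)
  y <- sample_stream(exponential_stream(st$times, st$amplitudes, alpha = alpha),
                     crit_kernel, Tper)
  z <- finite_difference(y, alpha)
  nr <- c(z$n_start, z$n_start + length(z$values) - 1L)
  zd <- sample_diracs(st, psi, Tper, n_range = nr)
  dco <- effective_coeffs(crit_kernel, alpha, Tper, crit_grid, nr)
  s_fd <- compute_moments(z, dco)
  s_dir <- compute_moments(zd, dco)
  expect_lt(max(abs(s_fd$s - s_dir$s)), 1e-8)
})

test_that("estimate_K finds the exact rank without noise and never returns 0", {
  # well-separated parameters: the signal singular values are comparable, so
  # any threshold clearly above the numerical floor recovers the rank
  u <- exp(1i * c(0.5, 2.4, 4.3))
  s <- synth_moments(c(1, 1.2, 0.9), u, 9)
  for (mu0 in c(1e-4, 0.1, 0.3)) expect_identical(estimate_K(s, mu0), 3L)
  expect_identical(estimate_K(synth_moments(1, exp(1i), 9), 0.3), 1L)

  set.seed(7)
  noise <- complex(real = rnorm(10), imaginary = rnorm(10))
  expect_gte(estimate_K(noise, 0.3), 1L)
  expect_error(estimate_K(s, 1.5), "mu0")
})
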