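test_that("soft thresholding shrinks magnitudes and preserves phase", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(0.5, 1), 0)
  v <- 4 * exp(1i * pi / 3)
  expect_equal(soft_threshold(v, 1), 3 * exp(1i * pi / 3), tolerance = 1e-14)
  expect_equal(soft_threshold(0 + 0i, 2), 0 + 0i)
  expect_error(soft_threshold(1, -0.1), ">= 0")
  # arrays keep their shape
  a <- array(c(-3, 0.2, 5, -0.1), c(2, 2))
  expect_equal(soft_threshold(a, 1), array(c(-2, 0, 4, 0), c(2, 2)))
})

test_that("soft thresholding minimizes the l1 proximal objective (grid oracle)", {
  # brute-force 2D grid search over candidate u in the complex plane
  set.seed(123)
  step <- 0.02
  for (case in 1:50) {
    v <- complex(real = rnorm(1), imaginary = rnorm(1)) * 1.5
    tau <- runif(1, 0, 2)
    lim <- Mod(v) + 0.5
    g <- seq(-lim, lim, by = step)
    cand <- outer(g, g, function(a, b) complex(real = a, imaginary = b))
    f <- tau * Mod(cand) + 0.5 * Mod(cand - v)^2
    u_grid <- cand[which.min(f)]
    u_st <- soft_threshold(v, tau)
    expect_lt(Mod(u_grid - u_st), 2 * step)
  }
})

test_that("SVT shrinks singular values and matches its examples", {
  D <- diag(c(3, 1)) + 0i
  out <- svt(D, 2)
  expect_equal(`attributes<-`(Mod(out), list(dim = c(2L, 2L))),
               diag(c(1, 0)), tolerance = 1e-12)
  expect_equal(attr(out, "rank"), 1L)
  # threshold at/above the largest singular value annihilates the matrix
  expect_true(all(Mod(svt(D, 3)) < 1e-12))
  expect_equal(attr(svt(D, 3), "rank"), 0L)
  # svt(D, 0) = D
  R <- random_complex_matrix(5, 7, seed = 3)
  expect_lt(max(Mod(svt(R, 0) - R)), 1e-12)
  expect_error(svt(matrix(c(1, NaN, 0, 1), 2), 1), "finite")
  expect_error(svt(R, -1), ">= 0")
})

test_that("SVT satisfies proximal optimality under random perturbations", {
  nuclear <- function(m) sum(svd(m, nu = 0, nv = 0)$d)
  F_obj <- function(A, D, tau) tau * nuclear(A) + 0.5 * sum(Mod(A - D)^2)
  set.seed(99)
  for (case in 1:20) {
    D <- random_complex_matrix(6, 6, seed = 200 + case)
    tau <- runif(1, 0.1, 3)
    A <- svt(D, tau)
    f0 <- F_obj(A, D, tau)
    for (p in 1:100) {
      delta <- matrix(complex(real = rnorm(36), imaginary = rnorm(36)),
                      6, 6) * 0.01
      expect_gte(F_obj(A + delta, D, tau), f0 - 1e-12)
    }
  }
})

test_that("soft_threshold and svt are nonexpansive", {
  set.seed(7)
  for (case in 1:10) {
    a <- random_complex_matrix(6, 5, seed = 300 + case)
    b <- random_complex_matrix(6, 5, seed = 400 + case)
    tau <- runif(1, 0, 2)
    expect_lte(frob_diff <- sqrt(sum(Mod(soft_threshold(a, tau) -
                                           soft_threshold(b, tau))^2)),
               sqrt(sum(Mod(a - b)^2)) + 1e-12)
    expect_lte(sqrt(sum(Mod(svt(a, tau) - svt(b, tau))^2)),
               sqrt(sum(Mod(a - b)^2)) + 1e-10)
  }
})

test_that("default parameter rules match their closed forms", {
  expect_equal(default_lambda(256, 256, 25), 1 / 256)
  expect_equal(default_lambda(1, 1, 30), 1 / sqrt(30))
  expect_equal(default_lambda(5, 4, 20), 1 / sqrt(20))  # both branches equal
  expect_equal(default_mu0(diag(c(2, 1)) + 0i), 0.75)
  # homogeneity: scaling X by c scales mu0 by 1/c
  X <- random_complex_matrix(6, 4, seed = 5)
  expect_equal(default_mu0(3 * X), default_mu0(X) / 3, tolerance = 1e-12)
  expect_error(default_mu0(matrix(0i, 3, 3)), "zero")
})

test_that("default mu0 agrees with a power-iteration spectral norm", {
  X <- random_complex_matrix(10, 5, seed = 8)
  # independent oracle: power iteration on X^H X
  v <- complex(real = rnorm(5), imaginary = rnorm(5))
  for (i in 1:500) {
    v <- Conj(t(X)) %*% (X %*% v)
    v <- v / sqrt(sum(Mod(v)^2))
  }
  sigma_max <- sqrt(Re(sum(Conj(v) * (Conj(t(X)) %*% (X %*% v)))))
  expect_equal(default_mu0(X), 1.5 / sigma_max, tolerance = 1e-8)
})

test_that("IALM recovers a pure low-rank matrix with negligible sparse part", {
  set.seed(11)
  u <- rnorm(100); v <- rnorm(20)
  X <- outer(u, v) + 0i
  fit <- ialm_rpca(X)
  expect_true(fit$converged)
  expect_lt(rel_frob(fit$A, X), 1e-5)
  expect_lt(sqrt(sum(Mod(fit$E)^2)) / sqrt(sum(Mod(X)^2)), 1e-5)
  expect_equal(fit$rank_history[fit$iterations], 1L)
})

test_that("IALM on the zero matrix returns the trivial decomposition", {
  fit <- ialm_rpca(matrix(0i, 4, 3))
  expect_true(all(fit$A == 0) && all(fit$E == 0))
  expect_true(fit$converged)
  expect_lte(fit$iterations, 1L)
})

test_that("IALM internals: exact mu schedule and feasibility identity", {
  p <- planted_rpca(n = 40, rank = 3, seed = 17)
  fit <- ialm_rpca(p$X, lambda = 1 / sqrt(40))
  expect_true(fit$converged)
  k <- fit$iterations
  # mu_k = mu0 * rho^k
  expect_equal(fit$mu_history, fit$mu0 * fit$rho^(0:(k - 1)),
               tolerance = 1e-12)
  expect_true(all(diff(fit$mu_history) > 0))
  # X - A_k - E_k = (L_k - L_{k-1}) / mu_{k-1}, checked at every iteration
  expect_true(all(is.finite(fit$feasibility_gap)))
  expect_lt(max(fit$feasibility_gap), 1e-10)
  # final relative residual beats the tolerance
  expect_lt(fit$residual_history[k], fit$tol)
})

test_that("IALM exactly recovers a planted rank-5 plus 5%-sparse matrix", {
  p <- planted_rpca(n = 100, rank = 5, sparsity = 0.05, seed = 1)
  fit <- ialm_rpca(p$X, lambda = 0.1)
  expect_true(fit$converged)
  expect_lt(rel_frob(fit$A, p$A0), 1e-4)
  expect_equal(fit$rank_history[fit$iterations], 5L)
  # recovered sparse part matches the plant on its support
  expect_lt(max(Mod(fit$E - p$E0)), 1e-2)
})

test_that("non-convergence at max_iter is flagged, not an error", {
  p <- planted_rpca(n = 30, rank = 2, seed = 23)
  fit <- ialm_rpca(p$X, max_iter = 3)
  expect_false(fit$converged)
  expect_equal(fit$iterations, 3L)
  expect_length(fit$residual_history, 3L)
})

test_that("the temporal Fourier transform is unitary and invertible", {
  M <- random_complex_matrix(30, 8, seed = 31)
  Tm <- ktlps:::temporal_fft(M)
  expect_equal(sqrt(sum(Mod(Tm)^2)), sqrt(sum(Mod(M)^2)), tolerance = 1e-12)
  expect_lt(max(Mod(ktlps:::temporal_ifft(Tm) - M)), 1e-12)
  # per-row Parseval
  expect_equal(rowSums(Mod(Tm)^2), rowSums(Mod(M)^2), tolerance = 1e-12)
})

test_that("x-f shrinkage equals the proximal map computed in x-f space", {
  M <- random_complex_matrix(20, 6, seed = 37)
  tau <- 0.3
  direct <- ktlps:::temporal_ifft(soft_threshold(ktlps:::temporal_fft(M), tau))
  # equivalent route: solve the prox in x-f coordinates, then invert
  xf <- ktlps:::temporal_fft(M)
  prox <- xf * ifelse(Mod(xf) > tau, (Mod(xf) - tau) / Mod(xf), 0)
  expect_lt(max(Mod(direct - ktlps:::temporal_ifft(prox))), 1e-13)
})

test_that("plain-mode reconstruction reproduces the zero-filled image as A+E", {
  ph <- generate_phantom(phantom_config(nx = 24, ny = 24, nt = 8, seed = 5))
  m <- radial_mask(mask_spec("radial", 24, 24, 8, n_spokes = 8, seed = 2))
  y <- forward(ph$X0, m)
  rec <- reconstruct(y, solver_config(mode = "plain", tol = 1e-7))
  X0 <- to_casorati(rec$zero_filled)
  AE <- rec$decomposition$A + rec$decomposition$E
  expect_lt(rel_frob(AE, unclass(X0)), 1e-6)
  expect_identical(unclass(rec$reconstruction),
                   unclass(from_casorati(ktlps:::as_casorati(AE, dim(y)))))
})

test_that("a full-mask acquisition reconstructs the ground truth in either mode", {
  ph <- generate_phantom(phantom_config(nx = 16, ny = 16, nt = 6, seed = 9))
  y <- forward(ph$X0, full_mask(16, 16, 6))
  for (mode in c("plain", "data_consistency")) {
    rec <- reconstruct(y, solver_config(mode = mode))
    expect_lt(rel_frob(unclass(rec$reconstruction), unclass(ph$X0)), 1e-4)
  }
})

test_that("solver configuration validates its parameters", {
  expect_error(solver_config(rho = 1), "> 1")
  expect_error(solver_config(lambda = -1), "positive")
  expect_error(solver_config(tol = 0), "positive")
  expect_error(solver_config(max_iter = 0), ">= 1")
  y0 <- ktdata(array(0i, c(4, 4, 1)),
               new_mask <- structure(array(0L, c(4, 4, 1)), scheme = "custom",
                                     spec = list(), class = "sampling_mask"))
  expect_error(reconstruct(y0), "empty")
})

test_that("tidy and glance summarize a fit", {
  p <- planted_rpca(n = 30, rank = 2, seed = 41)
  fit <- ialm_rpca(p$X)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), fit$iterations)
  expect_named(td, c("iteration", "residual", "rank", "mu"))
  gl <- glance(fit)
  expect_equal(gl$final_rank, fit$rank_history[fit$iterations])
  expect_true(gl$converged)
})
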