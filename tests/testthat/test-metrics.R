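test_that("energy-normalized PSNR matches its closed forms", {
  x <- random_sequence(8, 8, 4, seed = 51)
  expect_equal(psnr(x, x), Inf)
  zero <- dmri_sequence(array(0i, c(8, 8, 4)))
  # all-zero estimate: error energy equals signal energy -> 0 dB
  expect_equal(psnr(zero, x), 0)
  expect_error(psnr(x, zero), "all zero")
  expect_error(psnr(x, random_sequence(4, 4, 4, seed = 1)), "shape")
})

test_that("a 10% relative-energy magnitude perturbation scores 20 dB", {
  set.seed(53)
  b <- array(abs(rnorm(8 * 8 * 5)) + 1, c(8, 8, 5))
  e <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  e <- e * 0.1 * sqrt(sum(b^2)) / sqrt(sum(e^2))
  # keep magnitudes positive so |b + e| - |b| = e exactly
  stopifnot(all(b + e > 0))
  expect_equal(psnr(dmri_sequence(b + e), dmri_sequence(b)), 20,
               tolerance = 1e-12)
})

test_that("PSNR is a pure energy ratio: scale-invariant, noise-monotone", {
  x <- random_sequence(10, 10, 3, seed = 57)
  set.seed(58)
  noise <- array(rnorm(300), c(10, 10, 3))
  xh <- dmri_sequence(unclass(x) + noise)
  expect_equal(psnr(xh, x),
               psnr(dmri_sequence(3.7 * unclass(xh)),
                    dmri_sequence(3.7 * unclass(x))),
               tolerance = 1e-12)
  # strictly decreasing as the noise grows
  b <- array(abs(rnorm(300)) + 2, c(10, 10, 3))
  vals <- vapply(c(0.01, 0.05, 0.1, 0.5, 1), function(s) {
    psnr(dmri_sequence(b + s * abs(noise)), dmri_sequence(b))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("peak-based PSNR differs from the energy-normalized one as expected", {
  set.seed(59)
  b <- array(abs(rnorm(64)) + 1, c(4, 4, 4))
  xh <- dmri_sequence(b + 0.05)
  x <- dmri_sequence(b)
  # peak^2 * N / energy is the exact offset between the two definitions
  offset <- 10 * log10(max(b)^2 * length(b) / sum(b^2))
  expect_equal(psnr_peak(xh, x), psnr(xh, x) + offset, tolerance = 1e-10)
})

test_that("SSIM constants and the identical-frame case are exact", {
  p <- ssim_params()
  expect_equal(p$c1, 6.5025)
  expect_equal(p$c2, 58.5225)
  f <- matrix(runif(64, 0, 255), 8, 8)
  expect_equal(ssim_frame(f, f), 1.0)
  expect_error(ssim_frame(f, matrix(0, 4, 4)), "shape")
})

test_that("a constant offset reproduces the closed-form luminance penalty", {
  set.seed(61)
  f <- matrix(runif(144, 20, 200), 12, 12)
  off <- 30
  p <- ssim_params()
  got <- ssim_frame(f + off, f, p)
  mu <- mean(f)
  # structure/contrast term is exactly 1; only luminance differs
  expected <- (2 * mu * (mu + off) + p$c1) / (mu^2 + (mu + off)^2 + p$c1)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_lt(got, 1)
})

test_that("SSIM is symmetric, bounded, and 1 only at equality", {
  set.seed(63)
  for (case in 1:5) {
    a <- matrix(runif(100, 0, 255), 10, 10)
    b <- matrix(runif(100, 0, 255), 10, 10)
    expect_equal(ssim_frame(a, b), ssim_frame(b, a), tolerance = 1e-14)
    expect_lte(ssim_frame(a, b), 1)
    expect_gte(ssim_frame(a, b), -1)
    expect_lt(ssim_frame(a, b), 1 - 1e-6)
  }
})

test_that("per-frame SSIM localizes a single corrupted frame", {
  x <- random_sequence(8, 8, 5, seed = 67)
  s <- ssim_series(x, x)
  expect_equal(s, rep(1, 5))
  y <- unclass(x)
  y[, , 3] <- y[, , 3] + 40
  s2 <- ssim_series(dmri_sequence(y), x)
  expect_equal(s2[-3], rep(1, 4))
  expect_lt(s2[3], 1)
})

test_that("series SSIM is invariant to simultaneous spatial transposition", {
  a <- random_sequence(7, 7, 4, seed = 71)
  b <- random_sequence(7, 7, 4, seed = 72)
  ta <- dmri_sequence(aperm(unclass(a), c(2, 1, 3)))
  tb <- dmri_sequence(aperm(unclass(b), c(2, 1, 3)))
  expect_equal(ssim_series(a, b), ssim_series(ta, tb), tolerance = 1e-12)
})

test_that("windowed SSIM agrees with global SSIM on identical images", {
  f <- matrix(runif(400, 0, 255), 20, 20)
  expect_equal(ssim_frame(f, f, method = "window", window_size = 7), 1.0)
  g <- f + matrix(rnorm(400, sd = 10), 20, 20)
  w <- ssim_frame(abs(g), f, method = "window")
  expect_true(w > -1 && w < 1)
  expect_error(ssim_frame(f, f, method = "window", window_size = 25),
               "window_size")
})
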