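test_that("Cartesian line counts give the exact sampling ratio", {
  m4 <- cartesian_mask(mask_spec("cartesian", 32, 256, 3, acceleration = 4,
                                 seed = 1))
  expect_equal(sampling_ratio(m4), 64 / 256)
  m1 <- cartesian_mask(mask_spec("cartesian", 16, 64, 2, acceleration = 1,
                                 seed = 1))
  expect_equal(sampling_ratio(m1), 1.0)
  # round(256 / 6) = 43 lines; count the entries directly
  m6 <- cartesian_mask(mask_spec("cartesian", 8, 256, 2, acceleration = 6,
                                 seed = 5))
  for (t in 1:2) {
    lines <- which(colSums(unclass(m6)[, , t]) > 0)
    expect_length(lines, 43L)
    expect_true(all(colSums(unclass(m6)[, , t])[lines] == 8))
  }
  expect_equal(sampling_ratio(m6), 43 / 256)
})

test_that("Cartesian ratio is seed-independent and masks are seed-reproducible", {
  specs <- lapply(c(2, 9, 33), function(s) {
    mask_spec("cartesian", 8, 64, 4, acceleration = 3, seed = s)
  })
  ratios <- vapply(specs, function(sp) sampling_ratio(cartesian_mask(sp)),
                   numeric(1))
  expect_true(all(ratios == round(64 / 3) / 64))
  a <- cartesian_mask(specs[[1]])
  b <- cartesian_mask(specs[[1]])
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a), unclass(cartesian_mask(specs[[2]]))))
})

test_that("vary_per_frame controls frame-to-frame incoherence", {
  sp <- mask_spec("cartesian", 4, 128, 6, acceleration = 4, seed = 3,
                  vary_per_frame = TRUE)
  m <- unclass(cartesian_mask(sp))
  frames_differ <- any(vapply(2:6, function(t) {
    !identical(m[, , t], m[, , 1])
  }, logical(1)))
  expect_true(frames_differ)
  sp2 <- mask_spec("cartesian", 4, 128, 6, acceleration = 4, seed = 3,
                   vary_per_frame = FALSE)
  m2 <- unclass(cartesian_mask(sp2))
  for (t in 2:6) expect_identical(m2[, , t], m2[, , 1])
})

test_that("invalid mask specs are rejected", {
  expect_error(mask_spec("cartesian", 8, 8, 2, acceleration = 9), "exceeds")
  expect_error(mask_spec("cartesian", 8, 8, 2), "acceleration")
  expect_error(mask_spec("radial", 8, 8, 2), "n_spokes")
  expect_error(mask_spec("radial", 8, 8, 2, n_spokes = 0), ">= 1")
  expect_error(mask_spec("cartesian", 8, 8, 2, acceleration = 2,
                         center_fraction = 1), "center_fraction")
})

test_that("single axis-aligned spokes rasterize to full grid lines", {
  sp <- mask_spec("radial", 256, 256, 1, n_spokes = 1, seed = 1,
                  vary_per_frame = FALSE)
  m <- radial_mask(sp)
  expect_equal(sum(unclass(m)), 256L)
  expect_equal(sampling_ratio(m), 256 / 65536)
  # two orthogonal spokes: union of a row and a column sharing the center
  sp2 <- mask_spec("radial", 256, 256, 1, n_spokes = 2, seed = 1,
                   vary_per_frame = FALSE)
  m2 <- radial_mask(sp2)
  expect_equal(sum(unclass(m2)), 2L * 256L - 1L)
})

test_that("radial ratio is monotone nondecreasing in spoke count", {
  ratios <- vapply(c(2, 4, 8, 16, 32, 200), function(ns) {
    sampling_ratio(radial_mask(mask_spec("radial", 32, 32, 2, n_spokes = ns,
                                         seed = 1)))
  }, numeric(1))
  expect_true(all(diff(ratios) >= 0))
  # saturation is allowed, never an error
  sat <- radial_mask(mask_spec("radial", 16, 16, 1, n_spokes = 500, seed = 1))
  expect_lte(sampling_ratio(sat), 1)
})

test_that("74 radial spokes on a 256 grid sample about a quarter of k-space", {
  m <- radial_mask(mask_spec("radial", 256, 256, 1, n_spokes = 74, seed = 1))
  expect_equal(sampling_ratio(m), 0.25, tolerance = 0.02)
})

test_that("every frame of every mask contains the DC sample", {
  cx <- function(n) n %/% 2L + 1L
  masks <- list(
    cartesian_mask(mask_spec("cartesian", 16, 32, 4, acceleration = 8, seed = 2,
                             center_fraction = 0)),
    radial_mask(mask_spec("radial", 17, 23, 3, n_spokes = 3, seed = 4)),
    radial_mask(mask_spec("radial", 16, 16, 2, n_spokes = 2, seed = 4,
                          angle_scheme = "golden")),
    full_mask(5, 5, 2))
  for (m in masks) {
    d <- dim(m)
    for (t in seq_len(d[3])) {
      expect_equal(unclass(m)[cx(d[1]), cx(d[2]), t], 1L)
    }
  }
})
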