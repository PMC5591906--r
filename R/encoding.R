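#' Undersampled k-t space data
#'
#' Holds complex k-space samples for a 2D+time acquisition, zero at every
#' unsampled location, together with the sampling mask and the standard
#' deviation of any simulated measurement noise.
#'
#' @param samples complex array `c(nx, ny, nt)` of k-space values.
#' @param mask a `sampling_mask` of the same dimensions.
#' @param noise_sigma standard deviation of added complex Gaussian noise
#'   (same units as the samples; 0 means noiseless).
#' @return an object of class `ktdata`.
#' @export
ktdata <- function(samples, mask, noise_sigma = 0) {
  stopifnot(inherits(mask, "sampling_mask"))
  if (!is.array(samples) || !identical(dim(samples), dim(unclass(mask)))) {
    stop("samples and mask dimensions disagree", call. = FALSE)
  }
  if (!is.complex(samples)) samples <- samples + 0i
  if (any(samples[mask == 0L] != 0)) {
    stop("samples must be exactly zero at unsampled locations", call. = FALSE)
  }
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0", call. = FALSE)
  structure(samples, mask = mask, noise_sigma = noise_sigma, class = "ktdata")
}

#' @export
print.ktdata <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<ktdata> %d x %d x %d, ratio %.4f, sigma %.3g\n",
              d[1], d[2], d[3], sampling_ratio(attr(x, "mask")),
              attr(x, "noise_sigma")))
  invisible(x)
}

#' Masked Fourier encoding operator
#'
#' The measurement operator of the k-t acquisition model `Y = R F X + n`:
#' a centered, unitary 2D Fourier transform applied per frame (`F`),
#' followed by elementwise multiplication with the binary sampling mask
#' (`R`). The unitary convention makes Parseval exact, so with a full mask
#' `adjoint(forward(x)) == x` to machine precision, and the composition
#' `adjoint . forward` is an orthogonal projection in the image domain.
#'
#' @param mask a `sampling_mask`.
#' @return an object of class `encoding_operator`.
#' @export
encoding_operator <- function(mask) {
  stopifnot(inherits(mask, "sampling_mask"))
  structure(list(mask = mask), class = "encoding_operator")
}

#' Forward encoding: image series to undersampled k-t space
#'
#' Per frame, takes the centered unitary 2D Fourier transform of the image
#' and zeroes every unsampled location.
#'
#' @param x a [dmri_sequence()].
#' @param op an [encoding_operator()] (or a bare `sampling_mask`).
#' @return a [ktdata()] object.
#' @export
forward <- function(x, op) {
  mask <- if (inherits(op, "encoding_operator")) op$mask else op
  stopifnot(inherits(x, "dmri_sequence"), inherits(mask, "sampling_mask"))
  if (!identical(dim(x), dim(unclass(mask)))) {
    stop("image and mask dimensions disagree", call. = FALSE)
  }
  d <- dim(x)
  y <- array(0i, d)
  for (t in seq_len(d[3])) {
    y[, , t] <- fft2c(unclass(x)[, , t]) * (unclass(mask)[, , t] == 1L)
  }
  ktdata(y, mask, noise_sigma = 0)
}

#' Adjoint encoding: zero-filled reconstruction
#'
#' Per frame, the inverse centered unitary 2D Fourier transform of the
#' zero-filled k-space. With an undersampled mask this is the standard
#' "zero-filled" baseline reconstruction; with a full mask it inverts
#' [forward()] exactly.
#'
#' @param y a [ktdata()] object.
#' @param op optional [encoding_operator()]; defaults to the mask carried
#'   by `y`.
#' @param pixel_scale passed to the resulting [dmri_sequence()].
#' @return a [dmri_sequence()].
#' @export
adjoint <- function(y, op = NULL, pixel_scale = 255) {
  stopifnot(inherits(y, "ktdata"))
  if (!is.null(op)) {
    mask <- if (inherits(op, "encoding_operator")) op$mask else op
    if (!identical(dim(unclass(mask)), dim(unclass(y)))) {
      stop("k-space data and operator dimensions disagree", call. = FALSE)
    }
  }
  d <- dim(y)
  x <- array(0i, d)
  for (t in seq_len(d[3])) {
    x[, , t] <- ifft2c(unclass(y)[, , t])
  }
  dmri_sequence(x, pixel_scale = pixel_scale)
}

#' Add complex Gaussian measurement noise
#'
#' Adds i.i.d. Gaussian noise of standard deviation `sigma` independently
#' to the real and imaginary parts of every *sampled* k-space location;
#' unsampled locations stay exactly zero (noise is a property of the
#' measurement, not of the zero-filled gaps). Deterministic given `seed`.
#'
#' @param y a [ktdata()] object.
#' @param sigma noise standard deviation, in the units of the k-space
#'   samples (with images scaled to a 0-255 magnitude range and the unitary
#'   transform, sigma = 15 is roughly 6 percent of the DC peak).
#' @param seed integer seed.
#' @return a [ktdata()] with `noise_sigma` recorded.
#' @export
add_noise <- function(y, sigma, seed = 1L) {
  stopifnot(inherits(y, "ktdata"))
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  if (sigma == 0) return(y)
  mask <- attr(y, "mask")
  idx <- which(unclass(mask) == 1L)
  samples <- unclass(y)
  with_seed(seed, {
    n <- length(idx)
    samples[idx] <- samples[idx] +
      complex(real = stats::rnorm(n, sd = sigma),
              imaginary = stats::rnorm(n, sd = sigma))
  })
  ktdata(samples, mask, noise_sigma = sigma)
}
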