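#' Dynamic image sequence
#'
#' A `dmri_sequence` is a complex-valued 2D+time image series stored as an
#' `nx x ny x nt` array: the unknown image series `X` of the k-t acquisition
#' model. Real input is promoted to complex. `pixel_scale` records the nominal
#' dynamic range of the magnitudes (255 by convention, matching 8-bit
#' grayscale and the SSIM dynamic-range constants).
#'
#' @param values numeric or complex array of dimension `c(nx, ny, nt)`; a
#'   matrix is treated as a single frame.
#' @param pixel_scale nominal magnitude dynamic range (default 255).
#' @return a `dmri_sequence` (a complex array with attributes).
#' @examples
#' x <- dmri_sequence(array(rnorm(2 * 2 * 3), c(2, 2, 3)))
#' dim(x)
#' @export
dmri_sequence <- function(values, pixel_scale = 255) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("'values' must be an nx x ny x nt array", call. = FALSE)
  }
  if (any(dim(values) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  if (!is.complex(values)) {
    storage.mode(values) <- "double"
    values <- values + 0i
  }
  if (any(!is.finite(Re(values))) || any(!is.finite(Im(values)))) {
    stop("sequence values must be finite (no NaN/Inf)", call. = FALSE)
  }
  stopifnot_scalar(pixel_scale, "pixel_scale", positive = TRUE)
  structure(values, pixel_scale = pixel_scale, class = "dmri_sequence")
}

#' @export
print.dmri_sequence <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<dmri_sequence> %d x %d pixels, %d frames, |x| in [%.3g, %.3g]\n",
              d[1], d[2], d[3], min(Mod(x)), max(Mod(x))))
  invisible(x)
}

seq_dims <- function(x) {
  d <- dim(x)
  list(nx = d[1], ny = d[2], nt = d[3])
}

#' Casorati matrix of a dynamic sequence
#'
#' Reshapes a 2D+time series into its Casorati matrix: one column per
#' temporal frame, each frame flattened in column-major pixel order (R's
#' native array order). Temporal redundancy of the series appears as low
#' rank of this matrix; it is the object the low-rank plus sparse
#' decomposition operates on. The original shape is recorded so the
#' transform is losslessly invertible.
#'
#' @param seq a [dmri_sequence()].
#' @return a complex matrix of dimension `(nx*ny) x nt` with attribute
#'   `origin_shape`, class `casorati`.
#' @seealso [from_casorati()]
#' @export
to_casorati <- function(seq) {
  stopifnot(inherits(seq, "dmri_sequence"))
  d <- dim(seq)
  m <- unclass(seq)
  attr(m, "pixel_scale") <- NULL
  dim(m) <- c(d[1] * d[2], d[3])
  structure(m, origin_shape = d, class = "casorati")
}

#' Invert the Casorati reshaping
#'
#' Exact inverse of [to_casorati()]: reshapes a `(nx*ny) x nt` matrix back
#' into an `nx x ny x nt` [dmri_sequence()]. The round trip is bit-exact.
#'
#' @param mat a `casorati` matrix, or a plain matrix with `origin_shape`
#'   supplied.
#' @param origin_shape integer vector `c(nx, ny, nt)`; taken from the
#'   matrix attribute when omitted.
#' @param pixel_scale passed to [dmri_sequence()].
#' @export
from_casorati <- function(mat, origin_shape = NULL, pixel_scale = 255) {
  origin_shape <- origin_shape %||% attr(mat, "origin_shape")
  if (is.null(origin_shape)) {
    stop("'origin_shape' is required when the matrix carries none", call. = FALSE)
  }
  origin_shape <- as.integer(origin_shape)
  if (length(origin_shape) != 3L ||
      origin_shape[1] * origin_shape[2] != nrow(mat) ||
      origin_shape[3] != ncol(mat)) {
    stop(sprintf(
      "origin_shape (%s) is inconsistent with a %d x %d matrix",
      paste(origin_shape, collapse = ","), nrow(mat), ncol(mat)), call. = FALSE)
  }
  v <- unclass(mat)
  attr(v, "origin_shape") <- NULL
  dim(v) <- origin_shape
  dmri_sequence(v, pixel_scale = pixel_scale)
}

# Coerce a plain complex matrix to a casorati object for a known shape.
as_casorati <- function(mat, origin_shape) {
  structure(mat, origin_shape = as.integer(origin_shape), class = "casorati")
}
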