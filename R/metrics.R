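#' Energy-normalized peak signal-to-noise ratio
#'
#' `PSNR = -10 log10( ||Xhat - X||_F^2 / ||X||_F^2 )`, computed on the
#' magnitude images over the whole 2D+time array. Note that this variant
#' normalizes the error by the *signal energy*, not by the squared peak:
#' it is scale-invariant (a ratio of energies). The conventional
#' peak-based PSNR is available as [psnr_peak()].
#'
#' @param xhat reconstructed [dmri_sequence()] (or array).
#' @param x fully sampled reference, same shape, not all zero.
#' @return decibels; `Inf` when the images are identical.
#' @export
psnr <- function(xhat, x) {
  a <- Mod(unclass(xhat)); b <- Mod(unclass(x))
  if (!identical(dim(a), dim(b))) stop("shape mismatch", call. = FALSE)
  sig <- sum(b^2)
  if (sig == 0) stop("reference image is all zero", call. = FALSE)
  err <- sum((a - b)^2)
  if (err == 0) return(Inf)
  -10 * log10(err / sig)
}

#' Conventional peak-based PSNR
#'
#' `10 log10( peak^2 / MSE )` with `peak = max |X|` of the reference, the
#' textbook definition. Provided alongside the energy-normalized [psnr()]
#' for comparison with the wider literature.
#'
#' @inheritParams psnr
#' @export
psnr_peak <- function(xhat, x) {
  a <- Mod(unclass(xhat)); b <- Mod(unclass(x))
  if (!identical(dim(a), dim(b))) stop("shape mismatch", call. = FALSE)
  if (all(b == 0)) stop("reference image is all zero", call. = FALSE)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(b)^2 / mse)
}

#' SSIM stabilization parameters
#'
#' `c1 = (K1 * L)^2` and `c2 = (K2 * L)^2` with the standard values
#' `K1 = 0.01`, `K2 = 0.03` and dynamic range `L = 255` (8-bit grayscale).
#'
#' @param K1,K2 stabilization coefficients (> 0).
#' @param L dynamic range in grey levels (> 0).
#' @export
ssim_params <- function(K1 = 0.01, K2 = 0.03, L = 255) {
  stopifnot(K1 > 0, K2 > 0, L > 0)
  structure(list(K1 = K1, K2 = K2, L = L,
                 c1 = (K1 * L)^2, c2 = (K2 * L)^2),
            class = "ssim_params")
}

#' Structural similarity of two frames
#'
#' Global (single-window) SSIM:
#' `(2 mu_r mu_f + c1)(2 cov + c2) / ((mu_r^2 + mu_f^2 + c1)(var_r + var_f + c2))`
#' with means, variances (population convention, denominator `n`) and
#' covariance computed over the whole frame. Inputs are taken as
#' magnitude images already scaled to `[0, L]`. `method = "window"` gives
#' the common sliding-window variant (uniform `window_size` square moving
#' window, mean of the local SSIM map) for comparison with the wider
#' literature; the global statistic is the package's reference definition.
#'
#' @param xr,xf numeric matrices of the same shape (reconstructed and
#'   fully sampled frame).
#' @param params a [ssim_params()].
#' @param method `"global"` (default) or `"window"`.
#' @param window_size side of the square window for `method = "window"`.
#' @return a value in `[-1, 1]`; 1 iff the frames are identical.
#' @export
ssim_frame <- function(xr, xf, params = ssim_params(),
                       method = c("global", "window"), window_size = 11L) {
  method <- match.arg(method)
  xr <- Mod(unclass(xr)); xf <- Mod(unclass(xf))
  if (!identical(dim(xr), dim(xf))) stop("shape mismatch", call. = FALSE)
  if (method == "global") {
    n <- length(xr)
    mu_r <- mean(xr); mu_f <- mean(xf)
    var_r <- sum((xr - mu_r)^2) / n
    var_f <- sum((xf - mu_f)^2) / n
    cov_rf <- sum((xr - mu_r) * (xf - mu_f)) / n
    (2 * mu_r * mu_f + params$c1) * (2 * cov_rf + params$c2) /
      ((mu_r^2 + mu_f^2 + params$c1) * (var_r + var_f + params$c2))
  } else {
    ssim_window(xr, xf, params, as.integer(window_size))
  }
}

# Sliding uniform-window SSIM via box filtering with cumulative sums;
# local statistics use only fully interior windows.
ssim_window <- function(xr, xf, params, w) {
  if (w < 2L || w > min(dim(xr))) {
    stop("'window_size' must be between 2 and the smallest frame dimension",
         call. = FALSE)
  }
  box <- function(m) {
    cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed cumulative sum
    cs <- t(cs)
    pad <- rbind(0, cbind(0, cs))
    nr <- nrow(m) - w + 1L; nc <- ncol(m) - w + 1L
    i <- seq_len(nr); j <- seq_len(nc)
    pad[i + w, j + w, drop = FALSE] - pad[i, j + w, drop = FALSE] -
      pad[i + w, j, drop = FALSE] + pad[i, j, drop = FALSE]
  }
  n <- w * w
  mu_r <- box(xr) / n; mu_f <- box(xf) / n
  var_r <- box(xr^2) / n - mu_r^2
  var_f <- box(xf^2) / n - mu_f^2
  cov_rf <- box(xr * xf) / n - mu_r * mu_f
  smap <- (2 * mu_r * mu_f + params$c1) * (2 * cov_rf + params$c2) /
    ((mu_r^2 + mu_f^2 + params$c1) * (var_r + var_f + params$c2))
  mean(smap)
}

#' Per-frame SSIM of two dynamic series
#'
#' Applies [ssim_frame()] to the magnitude image of each temporal frame
#' independently. Both series are first rescaled to `[0, L]` by the
#' maximum magnitude of the *reference* series, so frame-to-frame
#' intensity differences are preserved and the stabilization constants
#' keep their 8-bit meaning.
#'
#' @param xr,xf [dmri_sequence()] objects (or arrays) of the same shape.
#' @param params a [ssim_params()].
#' @param ... passed to [ssim_frame()] (e.g. `method`).
#' @return numeric vector of length `nt`, in frame order.
#' @export
ssim_series <- function(xr, xf, params = ssim_params(), ...) {
  a <- Mod(unclass(xr)); b <- Mod(unclass(xf))
  if (!identical(dim(a), dim(b))) stop("shape mismatch", call. = FALSE)
  peak <- max(b)
  if (peak > 0) {
    s <- params$L / peak
    a <- a * s
    b <- b * s
  }
  vapply(seq_len(dim(a)[3]),
         function(t) ssim_frame(a[, , t], b[, , t], params, ...),
         numeric(1))
}
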