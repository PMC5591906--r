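#' Save undersampled k-t data to a container file
#'
#' Writes a self-describing container holding the complex k-space samples,
#' the 0/1 sampling mask, the mask's generator parameters and the noise
#' level. The save/load round trip is bit-exact. The container is a
#' serialized R list with a fixed schema (`kspace`, `mask`, `scheme`,
#' `params`, `noise_sigma`), validated field by field on load.
#'
#' @param data a [ktdata()] object.
#' @param path output file path (conventional extension `.ktr`).
#' @export
save_ktdata <- function(data, path) {
  stopifnot(inherits(data, "ktdata"))
  mask <- attr(data, "mask")
  obj <- list(format = "ktlps-ktdata", version = 1L,
              kspace = unclass(data),
              mask = unclass(mask),
              scheme = attr(mask, "scheme"),
              params = attr(mask, "spec"),
              noise_sigma = attr(data, "noise_sigma"))
  obj$kspace <- `attributes<-`(obj$kspace, list(dim = dim(unclass(data))))
  obj$mask <- `attributes<-`(obj$mask, list(dim = dim(unclass(mask))))
  saveRDS(obj, path)
  invisible(path)
}

#' Load undersampled k-t data from a container file
#'
#' Inverse of [save_ktdata()]. A container missing a required field, or
#' one whose samples and mask shapes disagree, raises a format error
#' naming the offending field.
#'
#' @param path file written by [save_ktdata()].
#' @return a [ktdata()] object.
#' @export
load_ktdata <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("not a readable ktlps container: ", conditionMessage(e), call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, "ktlps-ktdata")) {
    stop("format error: not a ktlps-ktdata container", call. = FALSE)
  }
  for (field in c("kspace", "mask", "scheme", "noise_sigma")) {
    if (is.null(obj[[field]])) {
      stop(sprintf("format error: missing field '%s'", field), call. = FALSE)
    }
  }
  if (!identical(dim(obj$kspace), dim(obj$mask))) {
    stop("format error: field 'mask' shape disagrees with 'kspace'",
         call. = FALSE)
  }
  spec <- obj$params %||% list(scheme = obj$scheme)
  mask <- new_sampling_mask(obj$mask, spec)
  ktdata(obj$kspace, mask, noise_sigma = obj$noise_sigma)
}

#' Export the magnitude series as NIfTI
#'
#' Writes the magnitude of a dynamic sequence as a 3D (x, y, t) NIfTI-1
#' volume for inspection in standard viewers. Requires the RNifti package.
#'
#' @param seq a [dmri_sequence()].
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_nifti_magnitude <- function(seq, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("package 'RNifti' is required for NIfTI export", call. = FALSE)
  }
  RNifti::writeNifti(RNifti::asNifti(Mod(unclass(seq))), path)
  invisible(path)
}

#' Import a magnitude series from NIfTI
#'
#' Reads a 3D (x, y, t) NIfTI volume as a real-valued [dmri_sequence()].
#'
#' @param path NIfTI file.
#' @param pixel_scale passed to [dmri_sequence()].
#' @export
read_nifti_magnitude <- function(path, pixel_scale = 255) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("package 'RNifti' is required for NIfTI import", call. = FALSE)
  }
  v <- RNifti::readNifti(path)
  dmri_sequence(array(as.numeric(v), dim(v)), pixel_scale = pixel_scale)
}

#' Export a single frame as PNG
#'
#' Writes the magnitude of one temporal frame as an 8-bit grayscale PNG,
#' scaled by the sequence maximum. Requires the png package.
#'
#' @param seq a [dmri_sequence()].
#' @param frame frame index.
#' @param path output path.
#' @export
write_frame_png <- function(seq, frame, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("package 'png' is required for PNG export", call. = FALSE)
  }
  d <- dim(seq)
  if (frame < 1L || frame > d[3]) stop("frame index out of range", call. = FALSE)
  img <- Mod(unclass(seq)[, , frame])
  img <- img / max(img, 1e-300)
  png::writePNG(t(img)[nrow(t(img)):1, , drop = FALSE], path)
  invisible(path)
}
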