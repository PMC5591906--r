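#' Sampling-mask specification
#'
#' Bundles the parameters of the two undersampling trajectories: Cartesian
#' variable-density random phase-encode lines, and pseudo-radial spokes
#' rasterized onto the Cartesian grid. Exactly one of `acceleration`
#' (Cartesian) or `n_spokes` (radial) drives the generator.
#'
#' @param scheme `"cartesian"` or `"radial"`.
#' @param nx,ny,nt k-space grid size and number of frames.
#' @param acceleration target acceleration factor R > 1 (Cartesian): the
#'   number of phase-encode lines kept per frame is `round(ny / R)`.
#' @param n_spokes number of radial spokes per frame (radial).
#' @param center_fraction fraction of central phase-encode lines always kept
#'   (Cartesian, default 1/32).
#' @param vary_per_frame draw a different mask per frame (default `TRUE`;
#'   frame-to-frame incoherence is what makes k-t reconstruction work).
#' @param angle_scheme `"uniform"` (equally spaced spokes with a small
#'   per-frame rotation) or `"golden"` (golden-angle increments).
#' @param seed integer seed; the mask is deterministic given the spec.
#' @return an object of class `mask_spec`.
#' @export
mask_spec <- function(scheme = c("cartesian", "radial"),
                      nx, ny, nt,
                      acceleration = NULL, n_spokes = NULL,
                      center_fraction = 1 / 32,
                      vary_per_frame = TRUE,
                      angle_scheme = c("uniform", "golden"),
                      seed = 1L) {
  scheme <- match.arg(scheme)
  angle_scheme <- match.arg(angle_scheme)
  nx <- as.integer(nx); ny <- as.integer(ny); nt <- as.integer(nt)
  stopifnot(nx >= 1L, ny >= 1L, nt >= 1L)
  if (scheme == "cartesian") {
    if (is.null(acceleration)) stop("cartesian scheme needs 'acceleration'", call. = FALSE)
    stopifnot_scalar(acceleration, "acceleration", positive = TRUE)
    if (acceleration > ny) {
      stop("'acceleration' exceeds the number of phase-encode lines", call. = FALSE)
    }
  } else {
    if (is.null(n_spokes)) stop("radial scheme needs 'n_spokes'", call. = FALSE)
    n_spokes <- as.integer(n_spokes)
    if (n_spokes < 1L) stop("'n_spokes' must be >= 1", call. = FALSE)
  }
  if (center_fraction < 0 || center_fraction >= 1) {
    stop("'center_fraction' must be in [0, 1)", call. = FALSE)
  }
  structure(list(scheme = scheme, nx = nx, ny = ny, nt = nt,
                 acceleration = acceleration, n_spokes = n_spokes,
                 center_fraction = center_fraction,
                 vary_per_frame = isTRUE(vary_per_frame),
                 angle_scheme = angle_scheme, seed = as.integer(seed)),
            class = "mask_spec")
}

new_sampling_mask <- function(indicator, spec) {
  storage.mode(indicator) <- "integer"
  structure(indicator, scheme = spec$scheme, spec = spec,
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<sampling_mask> %s, %d x %d x %d, ratio %.4f\n",
              attr(x, "scheme"), d[1], d[2], d[3], sampling_ratio(x)))
  invisible(x)
}

#' Fully sampled mask
#'
#' @param nx,ny,nt grid size and frames.
#' @export
full_mask <- function(nx, ny, nt) {
  spec <- list(scheme = "full", nx = nx, ny = ny, nt = nt)
  new_sampling_mask(array(1L, c(nx, ny, nt)), spec)
}

#' Cartesian variable-density line mask
#'
#' Keeps every readout (kx) sample on a random subset of phase-encode (ky)
#' lines. Exactly `round(ny / acceleration)` lines are kept per frame: a
#' central band of `round(center_fraction * ny)` lines around DC is always
#' included, and the remaining lines are drawn without replacement with
#' probability proportional to a zero-centered Gaussian over ky (standard
#' deviation `ny / 6`), so density is maximal at the k-space center. The
#' sampling ratio is therefore exactly `round(ny / acceleration) / ny`,
#' independent of the seed.
#'
#' @param spec a [mask_spec()] with `scheme = "cartesian"`.
#' @return a `sampling_mask`: integer 0/1 array of dimension
#'   `c(nx, ny, nt)`.
#' @export
cartesian_mask <- function(spec) {
  stopifnot(inherits(spec, "mask_spec"), spec$scheme == "cartesian")
  ny <- spec$ny; nt <- spec$nt
  n_lines <- max(1L, as.integer(round(ny / spec$acceleration)))
  cy <- dc_index(ny)
  # central band, clipped to the line budget but never dropping DC
  n_center <- min(max(1L, as.integer(round(spec$center_fraction * ny))), n_lines)
  half_lo <- (n_center - 1L) %/% 2L
  half_hi <- n_center - 1L - half_lo
  center_lines <- (cy - half_lo):(cy + half_hi)
  center_lines <- center_lines[center_lines >= 1L & center_lines <= ny]
  rest <- setdiff(seq_len(ny), center_lines)
  w <- exp(-((rest - cy)^2) / (2 * (ny / 6)^2))
  n_draw <- n_lines - length(center_lines)
  ind <- array(0L, c(spec$nx, ny, nt))
  with_seed(spec$seed, {
    draws <- if (spec$vary_per_frame) {
      lapply(seq_len(nt), function(t) {
        if (n_draw > 0L) sample(rest, n_draw, prob = w) else integer(0)
      })
    } else {
      one <- if (n_draw > 0L) sample(rest, n_draw, prob = w) else integer(0)
      rep(list(one), nt)
    }
    for (t in seq_len(nt)) ind[, c(center_lines, draws[[t]]), t] <- 1L
  })
  new_sampling_mask(ind, spec)
}

# Rasterize one spoke through the k-space center at angle theta onto an
# nx x ny grid: sample the continuous line at unit radial steps r in
# [-floor(n/2), floor(n/2)] and round each point to the nearest cell.
# Spokes are thereby confined to the inscribed disc (the usual
# pseudo-radial convention); an axis-aligned spoke is one full grid line.
rasterize_spoke <- function(nx, ny, theta) {
  cx <- dc_index(nx); cy <- dc_index(ny)
  r <- -(max(nx, ny) %/% 2L):(max(nx, ny) %/% 2L)
  i <- as.integer(round(cx + r * cos(theta)))
  j <- as.integer(round(cy + r * sin(theta)))
  keep <- i >= 1L & i <= nx & j >= 1L & j <= ny
  cbind(i[keep], j[keep])
}

#' Pseudo-radial spoke mask
#'
#' `n_spokes` straight lines through the k-space center at equally spaced
#' angles over `[0, pi)`, each sampled at unit radial steps and rasterized
#' to the Cartesian grid by nearest-cell rounding (spokes are confined to
#' the inscribed disc of the grid). With `vary_per_frame` the
#' spoke set of frame t is rotated by `(pi / n_spokes) * (t - 1) / nt`
#' (uniform scheme) or follows golden-angle increments (`angle_scheme =
#' "golden"`). A spoke count large enough to saturate the grid is allowed.
#' The DC sample is always included.
#'
#' @param spec a [mask_spec()] with `scheme = "radial"`.
#' @return a `sampling_mask`.
#' @export
radial_mask <- function(spec) {
  stopifnot(inherits(spec, "mask_spec"), spec$scheme == "radial")
  nx <- spec$nx; ny <- spec$ny; nt <- spec$nt
  ns <- spec$n_spokes
  golden <- pi * (sqrt(5) - 1) / 2
  ind <- array(0L, c(nx, ny, nt))
  for (t in seq_len(nt)) {
    angles <- if (spec$angle_scheme == "golden") {
      offset <- if (spec$vary_per_frame) (t - 1L) * ns else 0L
      ((seq_len(ns) - 1L + offset) * golden) %% pi
    } else {
      offset <- if (spec$vary_per_frame) (pi / ns) * (t - 1L) / nt else 0
      (seq_len(ns) - 1L) * pi / ns + offset
    }
    frame <- matrix(0L, nx, ny)
    for (a in angles) {
      cells <- rasterize_spoke(nx, ny, a)
      frame[cells] <- 1L
    }
    frame[dc_index(nx), dc_index(ny)] <- 1L
    ind[, , t] <- frame
  }
  new_sampling_mask(ind, spec)
}

#' Generate a sampling mask from a spec
#'
#' Dispatches to [cartesian_mask()] or [radial_mask()].
#' @param spec a [mask_spec()].
#' @export
generate_mask <- function(spec) {
  switch(spec$scheme,
         cartesian = cartesian_mask(spec),
         radial = radial_mask(spec),
         stop("unknown scheme: ", spec$scheme, call. = FALSE))
}

#' Sampling ratio of a mask
#'
#' Fraction of k-t samples acquired: number of indicator entries equal to 1
#' over `nx * ny * nt`. The acceleration factor is its reciprocal.
#'
#' @param mask a `sampling_mask`.
#' @return a number in (0, 1].
#' @export
sampling_ratio <- function(mask) {
  stopifnot(inherits(mask, "sampling_mask"))
  sum(mask == 1L) / length(mask)
}
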