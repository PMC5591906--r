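#' Phantom configuration
#'
#' Parameters of the synthetic dynamic phantom: a temporally correlated
#' background of known rank (a caricature of static anatomy with slow
#' contrast drift) plus a small number of periodically moving ellipses (a
#' beating-ventricle caricature) forming a spatially sparse dynamic
#' component with known support.
#'
#' @param nx,ny,nt grid size (pixels) and number of frames.
#' @param background_rank exact rank of the planted background Casorati
#'   matrix (`1 <= r <= min(nx*ny, nt)`).
#' @param n_dynamic number of moving ellipses (>= 0).
#' @param motion_amplitude peak center displacement over the cycle, pixels.
#' @param dynamic_intensity contrast of the moving objects, grey levels
#'   (on the 0-255 scale of the final phantom).
#' @param phase_roll add a smooth linear complex phase across the field of
#'   view, making the data genuinely complex (default `TRUE`).
#' @param seed integer seed; the phantom is bit-reproducible given the
#'   config.
#' @export
phantom_config <- function(nx = 64L, ny = 64L, nt = 16L,
                           background_rank = 3L, n_dynamic = 2L,
                           motion_amplitude = 3, dynamic_intensity = 120,
                           phase_roll = TRUE, seed = 1L) {
  nx <- as.integer(nx); ny <- as.integer(ny); nt <- as.integer(nt)
  background_rank <- as.integer(background_rank)
  stopifnot(nx >= 4L, ny >= 4L, nt >= 1L)
  if (background_rank < 1L || background_rank > min(nx * ny, nt)) {
    stop("'background_rank' must be in [1, min(nx*ny, nt)]", call. = FALSE)
  }
  if (n_dynamic < 0) stop("'n_dynamic' must be >= 0", call. = FALSE)
  structure(list(nx = nx, ny = ny, nt = nt,
                 background_rank = background_rank,
                 n_dynamic = as.integer(n_dynamic),
                 motion_amplitude = motion_amplitude,
                 dynamic_intensity = dynamic_intensity,
                 phase_roll = isTRUE(phase_roll), seed = as.integer(seed)),
            class = "phantom_config")
}

# Smooth random spatial map: white noise low-pass filtered with a Gaussian
# kernel in the Fourier domain.
smooth_map <- function(nx, ny, cutoff = 0.08) {
  z <- matrix(stats::rnorm(nx * ny), nx, ny)
  kx <- (seq_len(nx) - dc_index(nx)) / nx
  ky <- (seq_len(ny) - dc_index(ny)) / ny
  g <- exp(-(outer(kx^2, ky^2, `+`)) / (2 * cutoff^2))
  sm <- Re(ifft2c(fft2c(z) * g))
  sm / max(abs(sm))
}

ellipse_mask <- function(nx, ny, cx, cy, rx, ry) {
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
}

#' Generate a synthetic dynamic phantom with planted structure
#'
#' Builds a ground-truth series `X0 = A0 + E0` where the background `A0`
#' is a sum of exactly `background_rank` separable terms (orthonormalized
#' smooth spatial maps times orthonormalized smooth temporal weights, the
#' first being an elliptical "torso" with constant weight, so its Casorati
#' matrix has exactly the planted rank) and the dynamic part `E0` consists
#' of `n_dynamic` ellipses whose centers and radii oscillate periodically
#' over the cycle. Magnitudes are scaled so `max |X0| = 255`; an optional
#' linear phase roll makes the data complex. All randomness is governed by
#' `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return an object of class `dmri_phantom`: list with `X0`, `A0`, `E0`
#'   ([dmri_sequence()] objects satisfying `X0 = A0 + E0` exactly),
#'   `dynamic_support` (logical `nx x ny x nt` array; `E0` is zero outside
#'   it and its fraction never exceeds 15 percent), and the `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  nx <- config$nx; ny <- config$ny; nt <- config$nt
  r <- config$background_rank
  with_seed(config$seed, {
    # --- background: exactly rank-r Casorati matrix ---
    torso <- ellipse_mask(nx, ny, (nx + 1) / 2, (ny + 1) / 2,
                          0.42 * nx, 0.46 * ny)
    xs <- matrix(seq_len(nx), nx, ny) / nx - 0.5
    ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE) / ny - 0.5
    s1 <- torso * (1 - 1.2 * (xs^2 + ys^2))
    S <- matrix(0, nx * ny, r)
    S[, 1] <- as.vector(s1)
    if (r > 1L) {
      for (i in 2:r) S[, i] <- as.vector(smooth_map(nx, ny) * torso) * 0.3
    }
    W <- matrix(0, nt, r)
    W[, 1] <- 1
    if (r > 1L) {
      tt <- seq_len(nt)
      for (i in 2:r) {
        W[, i] <- 0.25 * cos(2 * pi * (i - 1) * tt / nt + stats::runif(1, 0, 2 * pi))
      }
    }
    # orthonormalize both factors so the planted rank is exact and stable
    S <- qr.Q(qr(S)) %*% diag(x = sqrt(colSums(S^2)), nrow = r)
    W <- qr.Q(qr(W)) %*% diag(x = sqrt(colSums(W^2)), nrow = r)
    A0 <- array(S %*% t(W), c(nx, ny, nt))
    A0 <- A0 / max(abs(A0))

    # --- dynamic part: pulsating / translating ellipses ---
    E0 <- array(0, c(nx, ny, nt))
    if (config$n_dynamic > 0L) {
      for (obj in seq_len(config$n_dynamic)) {
        cx0 <- stats::runif(1, 0.35, 0.65) * nx
        cy0 <- stats::runif(1, 0.35, 0.65) * ny
        rx0 <- stats::runif(1, 0.05, 0.08) * nx
        ry0 <- stats::runif(1, 0.05, 0.08) * ny
        phase <- stats::runif(1, 0, 2 * pi)
        for (t in seq_len(nt)) {
          ang <- 2 * pi * (t - 1) / nt + phase
          cx <- cx0 + config$motion_amplitude * sin(ang)
          cy <- cy0 + config$motion_amplitude * cos(ang)
          # motion_amplitude = 0 freezes the object entirely (no pulsation
          # either), so a static object adds at most one to the rank
          pulse <- if (config$motion_amplitude > 0) 1 + 0.2 * sin(ang) else 1
          m <- ellipse_mask(nx, ny, cx, cy, rx0 * pulse, ry0 * pulse)
          E0[, , t][m] <- config$dynamic_intensity / 255
        }
      }
    }
    support <- E0 != 0
    frac <- mean(support)
    if (frac > 0.15) {
      stop(sprintf(
        "dynamic support covers %.1f%% of voxels (budget 15%%); use fewer or smaller objects",
        100 * frac), call. = FALSE)
    }

    X0 <- A0 + E0
    scale <- 255 / max(abs(X0))
    A0 <- A0 * scale
    E0 <- E0 * scale
    if (config$phase_roll) {
      ph <- exp(2i * pi * (0.6 * xs + 0.4 * ys))
      ph <- array(rep(ph, nt), c(nx, ny, nt))
      A0 <- A0 * ph
      E0 <- E0 * ph
    }
    X0 <- A0 + E0
  })
  structure(list(X0 = dmri_sequence(X0), A0 = dmri_sequence(A0),
                 E0 = dmri_sequence(E0), dynamic_support = support,
                 config = config),
            class = "dmri_phantom")
}

#' @export
print.dmri_phantom <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<dmri_phantom> %d x %d x %d, background rank %d, %d moving objects, support %.1f%%\n",
    cfg$nx, cfg$ny, cfg$nt, cfg$background_rank, cfg$n_dynamic,
    100 * mean(x$dynamic_support)))
  invisible(x)
}

#' Normalized correlation of sparse-component magnitudes
#'
#' Correlation (cosine similarity) between the magnitude of a recovered
#' sparse component and the planted one, evaluated over the planted
#' dynamic support.
#'
#' @param E recovered sparse component ([dmri_sequence()] or array).
#' @param E0 planted sparse component, same shape.
#' @param support logical array selecting the planted dynamic voxels.
#' @return value in `[0, 1]`; 1 for a perfect match up to scale.
#' @export
sparse_overlap <- function(E, E0, support) {
  a <- Mod(unclass(E))[support]
  b <- Mod(unclass(E0))[support]
  if (sum(a^2) == 0 || sum(b^2) == 0) return(0)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Run one fully seeded acquisition-to-evaluation scenario
#'
#' Reproduces the full experimental protocol on a synthetic phantom:
#' generate ground truth, undersample its k-space with the given mask,
#' optionally add complex Gaussian noise, reconstruct with the low-rank
#' plus sparse solver, and score the result (energy-normalized PSNR,
#' per-frame SSIM, and the overlap of the recovered sparse component with
#' the planted one).
#'
#' @param config a [phantom_config()].
#' @param mask_spec a [mask_spec()] matching the phantom dimensions.
#' @param sigma k-space noise standard deviation (default 0).
#' @param solver a [solver_config()].
#' @param noise_seed seed for the noise draw (default derived from the
#'   phantom seed).
#' @return a list with `phantom`, `mask`, `ktdata`, `zero_filled`,
#'   `recon` (a `ktlps_recon`), and `metrics` (a one-row [tibble::tibble()]
#'   with `sampling_ratio`, `psnr_zero_filled`, `psnr_recon`,
#'   `psnr_gain_db`, `mean_ssim_recon`, `sparse_overlap`).
#' @export
end_to_end_case <- function(config, mask_spec, sigma = 0,
                            solver = solver_config(),
                            noise_seed = config$seed + 1L) {
  stopifnot(inherits(config, "phantom_config"))
  ph <- generate_phantom(config)
  mask <- generate_mask(mask_spec)
  if (!identical(dim(unclass(mask)), dim(ph$X0))) {
    stop("mask and phantom dimensions disagree", call. = FALSE)
  }
  y <- forward(ph$X0, mask)
  if (sigma > 0) y <- add_noise(y, sigma, seed = noise_seed)
  rec <- reconstruct(y, solver)
  m <- tibble::tibble(
    sampling_ratio = sampling_ratio(mask),
    psnr_zero_filled = psnr(rec$zero_filled, ph$X0),
    psnr_recon = psnr(rec$reconstruction, ph$X0),
    psnr_gain_db = psnr(rec$reconstruction, ph$X0) -
      psnr(rec$zero_filled, ph$X0),
    mean_ssim_recon = mean(ssim_series(rec$reconstruction, ph$X0)),
    sparse_overlap = sparse_overlap(rec$E, ph$E0, ph$dynamic_support))
  list(phantom = ph, mask = mask, ktdata = y,
       zero_filled = rec$zero_filled, recon = rec, metrics = m)
}

#' Sweep reconstruction quality over sampling ratios
#'
#' Runs [end_to_end_case()] for a set of radial spoke counts (or Cartesian
#' accelerations) and collects the quality metrics, mirroring the
#' PSNR-versus-sampling-factor experiment.
#'
#' @param config a [phantom_config()].
#' @param spokes integer vector of spoke counts (radial sweep), or `NULL`.
#' @param accelerations numeric vector of acceleration factors (Cartesian
#'   sweep), or `NULL`.
#' @param sigma noise level.
#' @param solver a [solver_config()].
#' @param seed mask seed.
#' @return a [tibble::tibble()] with one row per setting.
#' @export
sampling_sweep <- function(config, spokes = NULL, accelerations = NULL,
                           sigma = 0, solver = solver_config(), seed = 1L) {
  stopifnot(xor(is.null(spokes), is.null(accelerations)))
  settings <- if (!is.null(spokes)) spokes else accelerations
  rows <- lapply(settings, function(s) {
    ms <- if (!is.null(spokes)) {
      mask_spec("radial", config$nx, config$ny, config$nt, n_spokes = s,
                seed = seed)
    } else {
      mask_spec("cartesian", config$nx, config$ny, config$nt,
                acceleration = s, seed = seed)
    }
    cbind(tibble::tibble(setting = s),
          end_to_end_case(config, ms, sigma = sigma, solver = solver)$metrics)
  })
  tibble::as_tibble(do.call(rbind, rows))
}
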