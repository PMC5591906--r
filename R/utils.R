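# Internal numerical helpers shared across modules.

frob <- function(x) sqrt(sum(Mod(x)^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' RNG state, so seeded generators never perturb the global stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Circular-shift index helper: result[i] = x[(i - s - 1) mod n + 1].
shift_idx <- function(n, s) ((seq_len(n) - 1L - s) %% n) + 1L

# fftshift / ifftshift for matrices: move DC (index 1) to/from the grid
# center at floor(n/2) + 1. They are exact inverses for every n.
fftshift2 <- function(m) {
  m[shift_idx(nrow(m), nrow(m) %/% 2L), shift_idx(ncol(m), ncol(m) %/% 2L),
    drop = FALSE]
}

ifftshift2 <- function(m) {
  m[shift_idx(nrow(m), -(nrow(m) %/% 2L)), shift_idx(ncol(m), -(ncol(m) %/% 2L)),
    drop = FALSE]
}

# Centered unitary 2D Fourier transform and its inverse. Unitary scaling
# makes Parseval exact: ||fft2c(x)||_F == ||x||_F.
fft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

ifft2c <- function(y) {
  fftshift2(stats::fft(ifftshift2(y), inverse = TRUE)) / sqrt(length(y))
}

# Index of the DC sample on a length-n centered grid.
dc_index <- function(n) n %/% 2L + 1L

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  }
  invisible(x)
}
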