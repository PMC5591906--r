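#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-iteration history of an IALM fit
#'
#' One row per iteration: relative feasibility residual, rank of the
#' low-rank iterate, and the penalty value.
#'
#' @param x an [ialm_rpca()] fit.
#' @param ... unused.
#' @return a [tibble::tibble()] with columns `iteration`, `residual`,
#'   `rank`, `mu`.
#' @method tidy ialm_rpca
#' @export
tidy.ialm_rpca <- function(x, ...) {
  tibble::tibble(iteration = seq_len(x$iterations),
                 residual = x$residual_history,
                 rank = x$rank_history,
                 mu = x$mu_history)
}

#' One-row summary of an IALM fit
#'
#' @param x an [ialm_rpca()] fit.
#' @param ... unused.
#' @method glance ialm_rpca
#' @export
glance.ialm_rpca <- function(x, ...) {
  tibble::tibble(
    iterations = x$iterations,
    converged = x$converged,
    final_residual = if (x$iterations) x$residual_history[x$iterations] else 0,
    final_rank = if (x$iterations) x$rank_history[x$iterations] else 0L,
    lambda = x$lambda, mu0 = x$mu0, rho = x$rho, tol = x$tol,
    transform = x$transform)
}

#' Outer-loop history of a reconstruction
#'
#' @param x a `ktlps_recon` object.
#' @param ... unused.
#' @method tidy ktlps_recon
#' @export
tidy.ktlps_recon <- function(x, ...) {
  tibble::tibble(outer_iteration = seq_along(x$outer_residuals),
                 relative_change = x$outer_residuals)
}

#' One-row summary of a reconstruction
#'
#' @param x a `ktlps_recon` object.
#' @param ... unused.
#' @method glance ktlps_recon
#' @export
glance.ktlps_recon <- function(x, ...) {
  d <- dim(x$reconstruction)
  tibble::tibble(nx = d[1], ny = d[2], nt = d[3],
                 mode = x$config$mode,
                 transform = x$config$transform,
                 outer_iterations = x$outer_iterations,
                 inner_iterations = x$decomposition$iterations,
                 inner_converged = x$decomposition$converged)
}

#' Convergence plot of an IALM fit
#'
#' Relative feasibility residual per iteration on a log scale. Requires
#' ggplot2.
#'
#' @param object an [ialm_rpca()] fit.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.ialm_rpca <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("package 'ggplot2' is required for autoplot", call. = FALSE)
  }
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = iteration, y = residual)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration",
                  y = "relative feasibility residual",
                  title = "IALM convergence") +
    ggplot2::theme_minimal()
}

#' Magnitude image of selected frames
#'
#' Raster plot of the magnitude of one or more temporal frames. Requires
#' ggplot2.
#'
#' @param object a [dmri_sequence()].
#' @param frames frame indices to show (default frame 1).
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.dmri_sequence <- function(object, frames = 1L, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("package 'ggplot2' is required for autoplot", call. = FALSE)
  }
  d <- dim(object)
  frames <- frames[frames >= 1L & frames <= d[3]]
  df <- do.call(rbind, lapply(frames, function(t) {
    m <- Mod(unclass(object)[, , t])
    data.frame(x = rep(seq_len(d[1]), d[2]),
               y = rep(seq_len(d[2]), each = d[1]),
               value = as.vector(m),
               frame = t)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~frame) +
    ggplot2::labs(fill = "|x|") +
    ggplot2::theme_void()
}

utils::globalVariables(c("iteration", "residual", "x", "y", "value", "frame"))
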