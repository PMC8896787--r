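#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a resource gain function
#'
#' @param object An `ri_gain` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ri_gain <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$theta, y = .data$g)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::labs(
      x = "orientation (deg)", y = "resource gain g",
      title = "Resource allocation over orientation space"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an orientation prior
#'
#' @param object An `ri_prior` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ri_prior <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$theta, y = .data$density)) +
    ggplot2::geom_line(colour = "#444444") +
    ggplot2::labs(x = "orientation (deg)", y = "prior density") +
    ggplot2::theme_minimal()
}

#' Plot a psychometric curve
#'
#' @param object An `ri_psych` tibble from [psychometric_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ri_psych <- function(object, ...) {
  ok <- !is.na(object$p_right)
  ggplot2::ggplot(object[ok, ], ggplot2::aes(x = .data$diff, y = .data$p_right)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$p_right - .data$se, ymax = .data$p_right + .data$se
    )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "verticality difference, right - left (deg)",
      y = "P(choose right)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an MDS embedding of discriminability
#'
#' @param object An `ri_mds` tibble from [mds_embedding()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ri_mds <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$dim1, y = .data$dim2,
    colour = verticality(.data$theta), label = .data$theta
  )) +
    ggplot2::geom_path(colour = "grey70") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_text(vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::scale_colour_viridis_c(name = "verticality") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
}

#' Plot the learned gain over a session
#'
#' Heatmap of the gain trajectory of a closed-loop learning run.
#'
#' @param object An `ri_rl_run` from [run_rl_session()].
#' @param every Plot every `every`-th trial row.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ri_rl_run <- function(object, every = 10, ...) {
  rows <- seq(1, nrow(object$g_trace), by = every)
  df <- tidyr::expand_grid(trial = rows, theta = object$grid)
  df$g <- as.vector(t(object$g_trace[rows, ]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$trial, fill = .data$g)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "g") +
    ggplot2::labs(x = "orientation (deg)", y = "trial") +
    ggplot2::theme_minimal()
}
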