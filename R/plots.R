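#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' bonded distributions, density profiles and fit convergence histories;
#' [plot_pore_kinetics()] draws per-pore area time series.
#'
#' @param object object to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @name smalpr-plots
NULL

#' @rdname smalpr-plots
#' @export
autoplot.sma_distribution <- function(object, ...) {
  xlab <- switch(attr(object, "kind"), length = "length (nm)",
                 angle = "angle (deg)", dihedral = "dihedral (deg)")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "density",
                  title = attr(object, "term_id")) +
    ggplot2::theme_minimal()
}

#' @rdname smalpr-plots
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("%s (nm)", attr(object, "axis")),
                  y = expression(number ~ density ~ (nm^-3))) +
    ggplot2::theme_minimal()
}

#' @rdname smalpr-plots
#' @export
autoplot.sma_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$metric_max)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$tol, linetype = "dashed") +
    ggplot2::labs(x = "iteration", y = "max per-term JSD (base 2)") +
    ggplot2::theme_minimal()
}

#' @rdname smalpr-plots
#' @param kinetics tibble from [pore_kinetics()].
#' @export
plot_pore_kinetics <- function(kinetics, ...) {
  ggplot2::ggplot(kinetics,
                  ggplot2::aes(x = .data$time, y = .data$area,
                               colour = factor(.data$track_id))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (ps)", y = expression(pore ~ area ~ (nm^2)),
                  colour = "pore") +
    ggplot2::theme_minimal()
}
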