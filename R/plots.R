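# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a bifurcation scan
#'
#' Readout steady-state branches against the control variable, stable
#' branches solid and unstable dashed.
#'
#' @param object A `bifurcation_scan`.
#' @param variable State coordinate to plot (default PrgB / product).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bifurcation_scan
#' @export
autoplot.bifurcation_scan <- function(object, variable = NULL, ...) {
  if (is.null(variable)) {
    variable <- if (object$model_id == "pcf10") "B" else "X"
  }
  tab <- tidy(object)
  ggplot2::ggplot(
    tab,
    ggplot2::aes(
      x = .data$control_value, y = .data[[variable]],
      colour = .data$stability, shape = .data$stability
    )
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = if (object$model_id == "pcf10") {
        "extracellular pheromone (nM)"
      } else {
        "precursor level (arb.u./volume)"
      },
      y = paste(variable, "steady state"),
      title = sprintf(
        "Steady-state branches (%s, k = %s)", object$model_id,
        object$k
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a population snapshot distribution
#'
#' Readout histogram/density at one or more snapshot times.
#'
#' @param object A `population_sim`.
#' @param variable Readout column (default PrgB / product).
#' @param at Snapshot times to show (default the final one).
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot population_sim
#' @export
autoplot.population_sim <- function(object, variable = NULL, at = NULL,
                                    bins = 40, ...) {
  if (is.null(variable)) {
    variable <- if (object$model_id == "pcf10") "B" else "X"
  }
  ts <- unique(object$snapshots$t)
  if (is.null(at)) at <- max(ts)
  tab <- object$snapshots[object$snapshots$t %in% at, ]
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data[[variable]])) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(!!quote(density))),
      bins = bins, fill = "grey70", colour = "grey40"
    ) +
    ggplot2::geom_density(colour = "firebrick") +
    ggplot2::labs(
      x = variable, y = "density",
      title = sprintf(
        "%s distribution (%s, %s)", variable, object$model_id,
        object$mode
      )
    ) +
    ggplot2::theme_minimal()
  if (length(at) > 1) {
    p <- p + ggplot2::facet_wrap(~t, scales = "free_y", labeller = ggplot2::label_both)
  }
  p
}

#' Plot the shared / mean environment trajectory of a run
#'
#' @param sim A `population_sim`.
#' @return A ggplot of `I_ext` against time (ribbon: across-cell spread of
#'   private copies for the single-cell model).
#' @export
plot_environment <- function(sim) {
  stopifnot(inherits(sim, "population_sim"))
  ggplot2::ggplot(sim$env, ggplot2::aes(x = .data$t, y = .data$I_ext)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$I_ext - .data$I_ext_sd,
        ymax = .data$I_ext + .data$I_ext_sd
      ),
      fill = "steelblue", alpha = 0.2
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "time", y = "extracellular inhibitor",
      title = sprintf("Environment trajectory (%s)", sim$mode)
    ) +
    ggplot2::theme_minimal()
}
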