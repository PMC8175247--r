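# ggplot2 visualisations. Plot rendering is a convenience layer; all tested
# quantities come from the tabular results the plots are drawn from.

#' Plot a reaction norm
#'
#' Draws the expected trait value over the norm's (or a supplied)
#' environmental range.
#'
#' @param object A [reaction_norm()].
#' @param xlim Environmental range to draw; defaults to the norm's domain
#'   (which must then be finite).
#' @param n Number of evaluation points.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot reaction_norm
#' @export
autoplot.reaction_norm <- function(object, xlim = NULL, n = 201, ...) {
  xlim <- xlim %||% object$domain
  if (any(!is.finite(xlim))) {
    abort_validation("Provide a finite `xlim` for norms with unbounded domain.")
  }
  grid <- tibble::tibble(x = seq(xlim[1], xlim[2], length.out = n))
  grid$y <- eval_norm(object, grid$x)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "environmental parameter x",
      y = "expected trait value E(y | x)",
      title = sprintf("Reaction norm: genotype %s (%s)",
                      object$genotype, object$shape)
    ) +
    ggplot2::theme_minimal()
}

#' Plot studies along the environmental gradient
#'
#' Forest-style plot of per-study effects (with `z * se` bars) ordered along
#' the environmental gradient, overlaid with the fitted conditional-effect
#' line; studies whose interval captures the conditional prediction are
#' distinguished from those that do not.
#'
#' @param object A `gradient_fit` from [conditional_effect_regression()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gradient_fit
#' @export
autoplot.gradient_fit <- function(object, ...) {
  s <- object$studies
  ggplot2::ggplot(s, ggplot2::aes(x = .data$x, y = .data$mean_effect)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_effect - object$z * .data$se,
                   ymax = .data$mean_effect + object$z * .data$se,
                   colour = .data$success),
      width = 0
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$success), size = 1.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted), colour = "black") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
      name = "captures prediction"
    ) +
    ggplot2::labs(
      x = "environmental gradient x", y = "effect size",
      title = "Study effects along the environmental gradient",
      subtitle = "line: inverse-variance weighted conditional effect"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a coverage comparison
#'
#' Coverage of the population-average effect by the classical and the
#' RLM-adjusted interval, with Wilson score error bars and the nominal level.
#'
#' @param object A `coverage_table` from [coverage_experiment()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coverage_table
#' @export
autoplot.coverage_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$procedure, y = .data$coverage)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$nominal),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = NULL, y = "coverage of the population-average effect",
      title = "Classical versus random-lab-model interval coverage"
    ) +
    ggplot2::theme_minimal()
}
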