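#' Conditional-effect regression along an environmental gradient
#'
#' When each study carries a measured environmental covariate, the collection
#' of effect sizes can be modelled as a linear function of the environment
#' (inverse-variance weighted least squares). Each study is then judged
#' against its own conditional prediction: a study "captures" the predicted
#' value when the prediction falls strictly inside the study's
#' `mean_effect +/- z * se` interval. This conditions replication on the
#' environment instead of demanding one environment-free effect.
#'
#' @param studies A tibble of study results with columns `mean_effect`, `se`
#'   (> 0) and `x` (at least 3 distinct values).
#' @param z Confidence multiplier for the per-study capture check.
#' @return An object of class `gradient_fit`: the weighted `lm` fit, the
#'   input studies augmented with `predicted` and `success`, and `z`.
#'   Methods: [tidy()], [glance()], [augment()], [autoplot()].
#' @export
conditional_effect_regression <- function(studies, z = 1.96) {
  check_number(z, "z", lower = 0, strict_lower = TRUE)
  studies <- as_study_df(studies, "studies", c("mean_effect", "se", "x"))
  if (anyNA(studies$x)) {
    abort(
      "All studies need a known environmental covariate `x`.",
      class = "reactnorm_missing_covariate_error"
    )
  }
  if (any(studies$se <= 0)) {
    abort_validation("Degenerate standard error: all `se` must be > 0.")
  }
  if (nrow(studies) < 3L || length(unique(studies$x)) < 2L) {
    if (length(unique(studies$x)) < 2L) {
      abort(
        paste("All studies share the same environmental value; the gradient is",
              "unidentifiable. Consider assess_naive()."),
        class = "reactnorm_collinearity_error"
      )
    }
    abort_validation("At least 3 studies with distinct `x` are required.")
  }
  fit <- lm(mean_effect ~ x, data = studies, weights = 1 / studies$se^2)
  studies <- studies |>
    dplyr::mutate(
      predicted = as.numeric(fitted(fit)),
      success = abs(.data$predicted - .data$mean_effect) < z * .data$se
    )
  structure(list(fit = fit, studies = studies, z = z), class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  co <- coef(x$fit)
  cat(sprintf(
    "<gradient_fit> %d studies; effect = %.4g + %.4g * x; %d/%d capture the conditional prediction (z = %s)\n",
    nrow(x$studies), co[[1]], co[[2]], sum(x$studies$success), nrow(x$studies),
    format(x$z)))
  invisible(x)
}
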