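# broom-style tidiers for fitted objects.

#' Tidy a conditional-effect regression
#'
#' @param x A `gradient_fit` from [conditional_effect_regression()].
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy gradient_fit
#' @export
tidy.gradient_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(co[, "Estimate"]), std.error = unname(co[, "Std. Error"]),
    statistic = unname(co[, "t value"]), p.value = unname(co[, "Pr(>|t|)"])
  )
}

#' @rdname tidy.gradient_fit
#' @return For `glance()`: a one-row model summary (`r.squared`, `sigma`,
#'   `nobs`, `n_success`, `capture_rate`, `z`).
#' @method glance gradient_fit
#' @export
glance.gradient_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared, sigma = s$sigma, nobs = nrow(x$studies),
    n_success = sum(x$studies$success),
    capture_rate = mean(x$studies$success), z = x$z
  )
}

#' @rdname tidy.gradient_fit
#' @return For `augment()`: the input studies with `predicted` (conditional
#'   effect at each study's environment) and `success` (prediction inside the
#'   study's interval).
#' @method augment gradient_fit
#' @export
augment.gradient_fit <- function(x, ...) {
  x$studies
}

#' Tidy random-lab-model estimates
#'
#' @param x An `rlm_estimate` from [rlm_contrast()].
#' @param ... Unused.
#' @return A tibble with one row per study: `term`, `estimate`, `std.error`
#'   (the adjusted SE), `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @method tidy rlm_estimate
#' @export
tidy.rlm_estimate <- function(x, ...) {
  tibble::tibble(
    term = paste0("effect", seq_len(nrow(x))),
    estimate = x$effect, std.error = x$se_adjusted,
    statistic = x$statistic, p.value = x$p.value,
    conf.low = x$conf.low, conf.high = x$conf.high
  )
}

#' @rdname tidy.rlm_estimate
#' @return For `glance()`: a one-row summary (`n_studies`, `s2_gxe`,
#'   `confidence`, `mean_widening` — mean ratio of adjusted to classical SE).
#' @method glance rlm_estimate
#' @export
glance.rlm_estimate <- function(x, ...) {
  tibble::tibble(
    n_studies = nrow(x), s2_gxe = x$s2_gxe[1],
    confidence = attr(x, "confidence"),
    mean_widening = mean(x$se_adjusted / x$se_classical)
  )
}

#' Tidy a GxE variance-component estimate
#'
#' @param x A `gxe_estimate` from [estimate_gxe_variance()].
#' @param ... Unused.
#' @return For `tidy()`: the per-lab effects the estimate is based on. For
#'   `glance()`: a one-row summary with `s2_gxe`, `between_var`,
#'   `mean_sampling_var`, `n_labs`.
#' @method tidy gxe_estimate
#' @export
tidy.gxe_estimate <- function(x, ...) {
  x$effects
}

#' @rdname tidy.gxe_estimate
#' @method glance gxe_estimate
#' @export
glance.gxe_estimate <- function(x, ...) {
  tibble::tibble(
    s2_gxe = x$s2_gxe, between_var = x$between_var,
    mean_sampling_var = x$mean_sampling_var, n_labs = x$n_labs
  )
}
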