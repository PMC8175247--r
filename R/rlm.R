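#' Random-lab-model adjusted standard error
#'
#' The random lab model widens the standard error of a two-group contrast by
#' a penalising GxE term, acknowledging that the effect would vary between
#' laboratories:
#' \deqn{SE = \sqrt{s^2 (1/n_1 + 1/n_2) + 2 s^2_{G \times E}}.}
#' With `s2_gxe = 0` this reduces exactly to the classical pooled-variance
#' standard error; it is strictly increasing in `s2_gxe`.
#'
#' @param s2 Pooled within-group variance (trait units squared, >= 0).
#' @param n1,n2 Per-arm sample sizes (>= 2).
#' @param s2_gxe GxE variance component `s2_GxE` (>= 0); the between-lab
#'   variance of the contrast is `2 * s2_gxe`.
#' @return The adjusted standard error (vectorised over its arguments).
#' @examples
#' rlm_se(4, 8, 8, 0.5)  # sqrt(2)
#' @export
rlm_se <- function(s2, n1, n2, s2_gxe) {
  if (!is.numeric(s2) || !is.numeric(s2_gxe) || anyNA(s2) || anyNA(s2_gxe) ||
      any(s2 < 0) || any(s2_gxe < 0)) {
    abort_validation("`s2` and `s2_gxe` must be nonnegative variances.")
  }
  if (!is.numeric(n1) || !is.numeric(n2) || any(n1 < 2) || any(n2 < 2) ||
      any(n1 %% 1 != 0) || any(n2 %% 1 != 0)) {
    abort_validation("`n1` and `n2` must be integer counts >= 2.")
  }
  sqrt(s2 * (1 / n1 + 1 / n2) + 2 * s2_gxe)
}

#' Random-lab-model contrast estimate
#'
#' Applies the adjusted yardstick to one or more study results: the effect
#' estimate keeps its value, its standard error is replaced by [rlm_se()],
#' and the confidence interval and test are computed against a Gaussian
#' reference (the penalty term carries no degrees of freedom). With
#' `s2_gxe > 0` the adjusted interval strictly contains the classical one.
#'
#' @param studies A tibble of study results with `mean_effect`, `s2`, `n1`,
#'   `n2` (one row per study).
#' @param s2_gxe GxE variance component used for the adjustment.
#' @param confidence Two-sided confidence level in (0, 1).
#' @return A tibble of class `rlm_estimate`: `effect`, `s2`, `n1`, `n2`,
#'   `s2_gxe`, `se_classical`, `se_adjusted`, `statistic`, `p.value`,
#'   `conf.low`, `conf.high`. Methods: [tidy()], [glance()].
#' @export
rlm_contrast <- function(studies, s2_gxe, confidence = 0.95) {
  studies <- as_study_df(studies, "studies", c("mean_effect", "s2", "n1", "n2"))
  check_number(s2_gxe, "s2_gxe", lower = 0)
  z <- z_from_confidence(confidence)
  se_cl <- rlm_se(studies$s2, studies$n1, studies$n2, 0)
  se_adj <- rlm_se(studies$s2, studies$n1, studies$n2, s2_gxe)
  stat <- studies$mean_effect / se_adj
  out <- tibble::tibble(
    effect = studies$mean_effect, s2 = studies$s2,
    n1 = studies$n1, n2 = studies$n2, s2_gxe = s2_gxe,
    se_classical = se_cl, se_adjusted = se_adj,
    statistic = stat, p.value = 2 * pnorm(-abs(stat)),
    conf.low = studies$mean_effect - z * se_adj,
    conf.high = studies$mean_effect + z * se_adj
  )
  structure(out, class = c("rlm_estimate", class(out)),
            confidence = confidence)
}

#' Method-of-moments estimate of the GxE variance component
#'
#' The GxE penalty cannot be estimated from a single experiment; across
#' laboratories it can. Per lab (and genotype) the observed effects `d_j`
#' scatter with variance (between-lab effect variance) + (mean sampling
#' variance), so the moment estimator is
#' `s2_gxe_hat = max(0, (var(d_j) - mean(v_j)) / 2)`, where `v_j` is each
#' effect's squared standard error and the division by 2 matches the
#' `2 * s2_gxe` parameterisation of the contrast variance. With several
#' genotypes, effects are centred within genotype and the between-lab
#' variance is pooled across genotypes.
#'
#' @param data A per-animal multi-lab tibble (as from [simulate_multilab()]),
#'   or a per-lab study-result tibble (as from [summarize_labs()]).
#' @return A list of class `gxe_estimate`: `s2_gxe`, `between_var`
#'   (variance of the per-lab effects), `mean_sampling_var`, `n_labs`, and
#'   the per-lab `effects` tibble. Methods: [tidy()], [glance()].
#' @export
estimate_gxe_variance <- function(data) {
  if (all(c("arm", "y") %in% names(data))) {
    data <- summarize_labs(data)
  }
  data <- as_study_df(data, "data", c("lab_id", "mean_effect", "se"))
  if (!"genotype" %in% names(data)) data$genotype <- "g1"
  n_labs <- length(unique(data$lab_id))
  if (n_labs < 3L) {
    abort(
      paste("Fewer than 3 laboratories: the GxE variance component cannot be",
            "estimated from (nearly) a single experiment."),
      class = "reactnorm_insufficient_replication_error"
    )
  }
  per_geno <- data |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(
      ss = sum((.data$mean_effect - mean(.data$mean_effect))^2),
      df = dplyr::n() - 1L, .groups = "drop"
    )
  between_var <- sum(per_geno$ss) / sum(per_geno$df)
  mean_v <- mean(data$se^2)
  structure(
    list(
      s2_gxe = max(0, (between_var - mean_v) / 2),
      between_var = between_var, mean_sampling_var = mean_v,
      n_labs = n_labs,
      effects = dplyr::select(data, dplyr::any_of(
        c("lab_id", "genotype", "mean_effect", "se", "n1", "n2", "x", "s2")))
    ),
    class = "gxe_estimate"
  )
}

#' @export
print.gxe_estimate <- function(x, ...) {
  cat(sprintf(
    "<gxe_estimate> s2_gxe = %.4g (between-lab effect var %.4g, mean sampling var %.4g, %d labs)\n",
    x$s2_gxe, x$between_var, x$mean_sampling_var, x$n_labs))
  invisible(x)
}

#' Coverage experiment: classical versus random-lab-model intervals
#'
#' Simulates many independent single-laboratory studies under a design and
#' environment distribution, and records how often the classical confidence
#' interval and the RLM-adjusted interval cover the population-average
#' treatment effect `delta0 + delta1 * E[X]`. With environment-dependent
#' effects (`delta1 != 0`) the classical interval is calibrated only for the
#' lab's own conditional effect and under-covers the population average; the
#' RLM interval trades power for realism and restores coverage.
#'
#' @param design A [study_design()]; its `n_labs` is ignored (each replicate
#'   is one fresh single-lab study).
#' @param env The environment distribution of the dominating factor.
#' @param n_replicates Number of simulated studies (>= 100).
#' @param s2_gxe_used `"oracle"` to inject the simulator's true value
#'   `delta1^2 * sd(X)^2 / 2`, or a nonnegative number.
#' @param confidence Nominal two-sided confidence level.
#' @param seed Integer seed.
#' @return A tibble of class `coverage_table`, one row per procedure
#'   (`classical`, `rlm`): `n`, `covered`, `coverage`, `conf.low`,
#'   `conf.high` (Wilson), `nominal`, `s2_gxe`.
#' @export
coverage_experiment <- function(design, env, n_replicates = 1000,
                                s2_gxe_used = "oracle", confidence = 0.95,
                                seed) {
  stopifnot(inherits(design, "study_design"), inherits(env, "environment_dist"))
  n_replicates <- check_count(n_replicates, "n_replicates", lower = 100L)
  z <- z_from_confidence(confidence)
  seed <- check_seed(seed)
  if (identical(s2_gxe_used, "oracle")) {
    s2_gxe <- if (design$standardization == "standardized") 0
              else design$delta1^2 * env$sd^2 / 2
  } else {
    check_number(s2_gxe_used, "s2_gxe_used", lower = 0)
    s2_gxe <- s2_gxe_used
  }
  wide <- design
  wide$n_labs <- n_replicates
  data <- simulate_multilab(wide, env, seed)
  res <- summarize_labs(data)
  true_effect <- design$delta0 + design$delta1 * env$mean
  se_cl <- res$se
  se_rlm <- rlm_se(res$s2, res$n1, res$n2, s2_gxe)
  cover <- function(se) {
    mean(res$mean_effect - z * se < true_effect &
           true_effect < res$mean_effect + z * se)
  }
  n <- nrow(res)
  rows <- purrr::map2_dfr(
    list(se_cl, se_rlm), c("classical", "rlm"),
    function(se, proc) {
      k <- round(cover(se) * n)
      ci <- wilson_ci(k, n, confidence)
      tibble::tibble(procedure = proc, n = n, covered = k, coverage = k / n,
                     conf.low = ci[["lower"]], conf.high = ci[["upper"]],
                     nominal = confidence, s2_gxe = s2_gxe)
    }
  )
  structure(rows, class = c("coverage_table", class(rows)))
}
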