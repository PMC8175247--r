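#' Small-effect environmental factors and their Gaussian limit
#'
#' After a dominating environmental factor has been accounted for, the
#' remaining environmental influences are modelled as many independent
#' zero-mean factors of small effect. By the central limit theorem their sum
#' is approximately Gaussian with variance equal to the sum of the factor
#' variances; this aggregate is what the multi-lab simulator draws per
#' laboratory as the latent lab offset.
#'
#' `se_factor_uniform()` and `se_factor_gaussian()` build individual factors;
#' `small_effect_ensemble()` collects them.
#'
#' @param half_width Half-width of a centred uniform factor: values in
#'   `(-half_width, half_width)`, variance `(2 half_width)^2 / 12`.
#' @param sd Standard deviation of a centred Gaussian factor.
#' @param factors List of factors, each a list with fields `sampler`
#'   (function of `n`) and `variance` (finite, > 0).
#' @return `small_effect_ensemble()` returns an object of class
#'   `small_effect_ensemble` with fields `factors`, `count`,
#'   `total_variance`.
#' @name small-effect
NULL

#' @rdname small-effect
#' @export
se_factor_uniform <- function(half_width) {
  check_number(half_width, "half_width", lower = 0, strict_lower = TRUE)
  force(half_width)
  list(sampler = function(n) runif(n, -half_width, half_width),
       variance = (2 * half_width)^2 / 12)
}

#' @rdname small-effect
#' @export
se_factor_gaussian <- function(sd) {
  check_number(sd, "sd", lower = 0, strict_lower = TRUE)
  force(sd)
  list(sampler = function(n) rnorm(n, 0, sd), variance = sd^2)
}

#' @rdname small-effect
#' @export
small_effect_ensemble <- function(factors) {
  if (!is.list(factors)) abort_validation("`factors` must be a list.")
  for (i in seq_along(factors)) {
    f <- factors[[i]]
    if (!is.list(f) || !is.function(f$sampler) || !is.numeric(f$variance) ||
        !is.finite(f$variance) || f$variance <= 0) {
      abort_validation(sprintf(
        "Factor %d must have a `sampler` function and a finite positive `variance`.", i))
    }
  }
  structure(
    list(factors = factors, count = length(factors),
         total_variance = sum(vapply(factors, `[[`, numeric(1), "variance"))),
    class = "small_effect_ensemble"
  )
}

#' Aggregate small-effect factors towards their Gaussian limit
#'
#' Draws `n_samples` sums of one independent draw per factor and reports the
#' limiting Gaussian parameters `(0, sqrt(sum of variances))`. An empty
#' ensemble degenerates to a point mass at 0 (with a warning).
#'
#' @param ensemble A [small_effect_ensemble()].
#' @param n_samples Number of aggregate draws (>= 2).
#' @param seed Integer seed.
#' @return A list of class `clt_aggregate` with fields `samples`,
#'   `limit_mean` (0), `limit_sd`, `count`.
#' @examples
#' ens <- small_effect_ensemble(replicate(20, se_factor_uniform(0.1), simplify = FALSE))
#' agg <- clt_aggregate(ens, n_samples = 1000, seed = 1)
#' sd(agg$samples); agg$limit_sd
#' @export
clt_aggregate <- function(ensemble, n_samples, seed) {
  stopifnot(inherits(ensemble, "small_effect_ensemble"))
  n_samples <- check_count(n_samples, "n_samples", lower = 2L)
  seed <- check_seed(seed)
  if (ensemble$count == 0L) {
    warn("Empty small-effect ensemble: aggregate is a point mass at 0.",
         class = "reactnorm_degenerate_warning")
    return(structure(list(samples = rep(0, n_samples), limit_mean = 0,
                          limit_sd = 0, count = 0L), class = "clt_aggregate"))
  }
  samples <- withr::with_seed(seed, {
    total <- numeric(n_samples)
    for (f in ensemble$factors) total <- total + f$sampler(n_samples)
    total
  })
  structure(
    list(samples = samples, limit_mean = 0,
         limit_sd = sqrt(ensemble$total_variance), count = ensemble$count),
    class = "clt_aggregate"
  )
}

#' @export
print.clt_aggregate <- function(x, ...) {
  cat(sprintf("<clt_aggregate> %d factors, %d samples; limit N(0, %s)\n",
              x$count, length(x$samples), format(x$limit_sd)))
  invisible(x)
}
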