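#' Environment distributions
#'
#' The state of the dominating environmental parameter across laboratories is
#' modelled by a probability density `g(x)` with a seedable sampler. Gaussian
#' and uniform families have closed-form moments; arbitrary measured densities
#' can be supplied as a tabulated grid and are normalised and sampled by
#' inverse-CDF interpolation.
#'
#' @param mean,sd Mean and standard deviation of the Gaussian family
#'   (environment units); `sd > 0`.
#' @param min,max Bounds of the uniform family.
#' @param x Grid of environmental values (strictly increasing) for the
#'   tabulated family.
#' @param density Nonnegative density values on the grid (normalised
#'   internally by trapezoidal integration).
#' @param file Optional 2-column CSV (`x,value`, header required) to read a
#'   tabulated density from.
#' @return An object of class `environment_dist` with fields `family`, `pdf`,
#'   `sampler` (function of `n`, uses the current RNG stream), `support`,
#'   `mean`, `sd`.
#' @name environment-distributions
NULL

new_environment_dist <- function(family, pdf, sampler, support, mean, sd) {
  structure(list(family = family, pdf = pdf, sampler = sampler,
                 support = as.numeric(support), mean = mean, sd = sd),
            class = "environment_dist")
}

#' @rdname environment-distributions
#' @export
env_gaussian <- function(mean = 0, sd = 1) {
  check_number(mean, "mean")
  check_number(sd, "sd", lower = 0, strict_lower = TRUE)
  force(mean); force(sd)
  new_environment_dist(
    "gaussian",
    pdf = function(x) dnorm(x, mean, sd),
    sampler = function(n) rnorm(n, mean, sd),
    support = c(-Inf, Inf), mean = mean, sd = sd
  )
}

#' @rdname environment-distributions
#' @export
env_uniform <- function(min = 0, max = 1) {
  check_number(min, "min"); check_number(max, "max")
  if (min >= max) abort_validation("`min` must be smaller than `max`.")
  force(min); force(max)
  new_environment_dist(
    "uniform",
    pdf = function(x) stats::dunif(x, min, max),
    sampler = function(n) runif(n, min, max),
    support = c(min, max), mean = (min + max) / 2, sd = (max - min) / sqrt(12)
  )
}

#' @rdname environment-distributions
#' @export
env_tabulated <- function(x, density = NULL, file = NULL) {
  if (!is.null(file)) {
    tab <- readr::read_csv(file, col_types = readr::cols(
      x = readr::col_double(), value = readr::col_double()
    ))
    x <- tab$x; density <- tab$value
  } else if (is.data.frame(x)) {
    if (!all(c("x", "value") %in% names(x))) {
      abort_validation("Tabulated density data frame needs columns `x` and `value`.")
    }
    density <- x$value; x <- x$x
  }
  if (length(x) < 2L || any(diff(x) <= 0) || anyNA(x) || anyNA(density)) {
    abort_validation("Tabulated density needs a strictly increasing grid without NA.")
  }
  if (any(density < 0)) abort_validation("Density values must be nonnegative.")
  xs <- as.numeric(x); ds <- as.numeric(density)
  total <- pracma::trapz(xs, ds)
  if (total <= 0) abort_validation("Tabulated density integrates to zero.")
  ds <- ds / total
  pdf <- approxfun(xs, ds, method = "linear", yleft = 0, yright = 0)
  # cumulative trapezoid for inverse-CDF sampling
  cdf <- c(0, cumsum(diff(xs) * (head(ds, -1) + ds[-1]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  inv <- approxfun(cdf[keep], xs[keep], method = "linear", rule = 2)
  mu <- pracma::trapz(xs, xs * ds)
  sigma <- sqrt(max(0, pracma::trapz(xs, (xs - mu)^2 * ds)))
  new_environment_dist(
    "tabulated", pdf = pdf, sampler = function(n) inv(runif(n)),
    support = range(xs), mean = mu, sd = sigma
  )
}

#' Check that an environment distribution is a proper density
#'
#' Integrates the pdf over the support (truncated at +/- 8 standard
#' deviations around the mean when unbounded) by adaptive quadrature and
#' checks normalisation to 1 within `tol`.
#'
#' @param env An `environment_dist`.
#' @param tol Numerical tolerance on the integral (default `1e-6`).
#' @return Invisibly, the computed integral. Errors if the check fails.
#' @export
check_environment <- function(env, tol = 1e-6) {
  stopifnot(inherits(env, "environment_dist"))
  lo <- env$support[1]; hi <- env$support[2]
  if (!is.finite(lo)) lo <- env$mean - 8 * env$sd
  if (!is.finite(hi)) hi <- env$mean + 8 * env$sd
  total <- integrate(env$pdf, lo, hi, rel.tol = tol / 10)$value
  if (abs(total - 1) > max(tol, 2e-15)) {
    abort_validation(sprintf(
      "Environment pdf integrates to %s over its (truncated) support, not 1.",
      format(total)))
  }
  invisible(total)
}

#' @export
print.environment_dist <- function(x, ...) {
  cat(sprintf("<environment_dist> family %s, support [%s, %s], mean %s, sd %s\n",
              x$family, format(x$support[1]), format(x$support[2]),
              format(x$mean), format(x$sd)))
  invisible(x)
}
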