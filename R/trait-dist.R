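#' Trait-value distributions
#'
#' The distribution `f` of expected trait values induced by pushing an
#' environment distribution through a reaction norm. Three representations
#' are supported: closed-form Gaussian, point mass (flat norm), and an
#' empirical Monte Carlo sample. All carry a first moment `M1` and expose
#' tail probabilities for the tail-product replication criterion.
#'
#' @param mean,sd Gaussian parameters (trait units); `sd > 0`.
#' @param value Location of the point mass.
#' @param samples Numeric sample of expected trait values.
#' @param seed Seed the sample was generated under (recorded for provenance).
#' @return An object of class `trait_dist`.
#' @name trait-distributions
NULL

new_trait_dist <- function(representation, ...) {
  structure(c(list(representation = representation), list(...)),
            class = "trait_dist")
}

#' @rdname trait-distributions
#' @export
trait_gaussian <- function(mean, sd) {
  check_number(mean, "mean")
  check_number(sd, "sd", lower = 0, strict_lower = TRUE)
  new_trait_dist("gaussian", mean = mean, sd = sd)
}

#' @rdname trait-distributions
#' @export
trait_pointmass <- function(value) {
  check_number(value, "value")
  new_trait_dist("pointmass", value = value)
}

#' @rdname trait-distributions
#' @export
trait_empirical <- function(samples, seed = NA_integer_) {
  if (!is.numeric(samples) || length(samples) < 2L || any(!is.finite(samples))) {
    abort_validation("`samples` must be >= 2 finite numbers.")
  }
  new_trait_dist("empirical", samples = as.numeric(samples),
                 sample_size = length(samples), seed = seed)
}

#' First moment of a trait distribution
#'
#' @param dist A `trait_dist`.
#' @return The first moment `M1` (trait units), the reference point for
#'   choosing tail sides in the tail-product criterion.
#' @export
m1 <- function(dist) {
  stopifnot(inherits(dist, "trait_dist"))
  switch(dist$representation,
    gaussian = dist$mean,
    pointmass = dist$value,
    empirical = mean(dist$samples)
  )
}

#' Tail probability of a trait distribution
#'
#' `P(Y > y)` (side `"upper"`) or `P(Y < y)` (side `"lower"`). For empirical
#' representations the raw empirical tail mass is used, with no smoothing.
#'
#' @param dist A `trait_dist`.
#' @param y Numeric vector of trait values.
#' @param side `"upper"` or `"lower"`.
#' @return Probabilities in `[0, 1]`, one per element of `y`.
#' @export
tail_prob <- function(dist, y, side = c("upper", "lower")) {
  stopifnot(inherits(dist, "trait_dist"))
  side <- match.arg(side)
  if (!is.numeric(y) || anyNA(y)) abort_validation("`y` must be numeric without NA.")
  lower <- side == "lower"
  switch(dist$representation,
    gaussian = pnorm(y, dist$mean, dist$sd, lower.tail = lower),
    pointmass = if (lower) as.numeric(dist$value < y) else as.numeric(dist$value > y),
    empirical = vapply(
      y,
      function(yy) if (lower) mean(dist$samples < yy) else mean(dist$samples > yy),
      numeric(1)
    )
  )
}

trait_variance <- function(dist) {
  switch(dist$representation,
    gaussian = dist$sd^2,
    pointmass = 0,
    empirical = var(dist$samples)
  )
}

#' Compose a reaction norm with an environment distribution
#'
#' Pushes the environment distribution through the norm to obtain the induced
#' distribution of expected trait values, `f = g(h(x))`. Closed forms exist
#' for exactly two cases: a flat norm gives a point mass at its constant, and
#' a linear norm `h(x) = a + b x` with `X ~ N(mu, sigma)` gives
#' `N(a + b mu, |b| sigma)`. Every other combination is composed by Monte
#' Carlo with a mandatory explicit seed; requesting `"closed_form"` there is
#' an error, never a silent fallback.
#'
#' @param norm A [reaction_norm()].
#' @param env An [env_gaussian()], [env_uniform()] or [env_tabulated()]
#'   environment distribution.
#' @param method `"closed_form"` or `"monte_carlo"`.
#' @param n_samples Number of Monte Carlo draws (>= 2).
#' @param seed Integer seed for the Monte Carlo draws.
#' @return A `trait_dist`.
#' @examples
#' compose_distribution(norm_linear(1, 2), env_gaussian(0, 1), "closed_form")
#' @export
compose_distribution <- function(norm, env,
                                 method = c("monte_carlo", "closed_form"),
                                 n_samples = 1e5, seed = NULL) {
  stopifnot(inherits(norm, "reaction_norm"), inherits(env, "environment_dist"))
  method <- match.arg(method)
  if (norm$domain[1] > env$support[1] || norm$domain[2] < env$support[2]) {
    mass_out <- env_mass_outside(env, norm$domain)
    if (mass_out >= 1e-9) {
      abort_domain(sprintf(
        "Environment places mass %.3g outside the norm's domain [%s, %s].",
        mass_out, format(norm$domain[1]), format(norm$domain[2])))
    }
  }
  if (method == "closed_form") {
    if (norm$shape == "flat") {
      return(trait_pointmass(eval_norm(norm, clamp_to(norm$domain, env$mean))))
    }
    if (norm$shape == "linear" && env$family == "gaussian") {
      p <- norm$params
      a <- p$intercept %||% p$a
      b <- p$slope %||% p$b
      if (is.null(a) || is.null(b)) {
        # linear norm built from a bare function: recover coefficients
        x0 <- if (all(is.finite(norm$domain))) mean(norm$domain) else env$mean
        b <- (norm$h(x0 + 0.5) - norm$h(x0 - 0.5))
        a <- norm$h(x0) - b * x0
      }
      return(trait_gaussian(a + b * env$mean, abs(b) * env$sd))
    }
    abort(
      sprintf(
        "No closed-form composition for shape `%s` with a `%s` environment; use method = \"monte_carlo\".",
        norm$shape, env$family),
      class = "reactnorm_unsupported_method_error"
    )
  }
  n_samples <- check_count(n_samples, "n_samples", lower = 2L)
  seed <- check_seed(seed)
  xs <- withr::with_seed(seed, env$sampler(n_samples))
  trait_empirical(eval_norm(norm, xs), seed = seed)
}

env_mass_outside <- function(env, domain) {
  lo <- max(env$support[1], if (is.finite(env$support[1])) env$support[1] else env$mean - 10 * env$sd)
  hi <- min(env$support[2], if (is.finite(env$support[2])) env$support[2] else env$mean + 10 * env$sd)
  below <- if (domain[1] > lo) integrate(env$pdf, lo, min(domain[1], hi))$value else 0
  above <- if (domain[2] < hi) integrate(env$pdf, max(domain[2], lo), hi)$value else 0
  below + above
}

clamp_to <- function(domain, x) min(max(x, domain[1]), domain[2])

#' @export
print.trait_dist <- function(x, ...) {
  desc <- switch(x$representation,
    gaussian = sprintf("Gaussian(mean = %s, sd = %s)", format(x$mean), format(x$sd)),
    pointmass = sprintf("point mass at %s", format(x$value)),
    empirical = sprintf("empirical, n = %d", x$sample_size)
  )
  cat(sprintf("<trait_dist> %s; M1 = %s\n", desc, format(m1(x))))
  invisible(x)
}
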