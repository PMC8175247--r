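#' Construct a reaction norm
#'
#' A reaction norm is a genotype-specific deterministic mapping `h` from the
#' value of an environmental parameter (e.g. ambient temperature) to the
#' expected value of a phenotypic trait, `E(y | x) = h(x)`, valid over a
#' stated environmental range. Different genotypes can carry different norms,
#' which is the source of genotype-by-environment (GxE) interaction.
#'
#' @param h A vectorised function of one numeric argument returning expected
#'   trait values.
#' @param domain Closed interval `c(lo, hi)` of valid environmental values.
#' @param genotype Genotype label (single string).
#' @param shape One of `"flat"`, `"linear"`, `"monotone"`, `"general"`; used
#'   to dispatch closed-form composition with an environment distribution.
#' @param params Named list of the parameters the norm was built from
#'   (recorded for printing and serialisation).
#' @return An object of class `reaction_norm`.
#' @seealso [norm_flat()], [norm_linear()], [norm_quadratic()],
#'   [norm_logistic()], [norm_tabulated()], [eval_norm()]
#' @export
reaction_norm <- function(h, domain = c(-Inf, Inf), genotype = "g1",
                          shape = c("general", "flat", "linear", "monotone"),
                          params = list()) {
  shape <- match.arg(shape)
  if (!is.function(h)) abort_validation("`h` must be a function.")
  if (!is.numeric(domain) || length(domain) != 2L || any(is.na(domain)) ||
      domain[1] >= domain[2]) {
    abort_validation("`domain` must be a numeric interval c(lo, hi) with lo < hi.")
  }
  if (!is.character(genotype) || length(genotype) != 1L || is.na(genotype)) {
    abort_validation("`genotype` must be a single string.")
  }
  structure(
    list(genotype = genotype, h = h, domain = as.numeric(domain),
         shape = shape, params = params),
    class = "reaction_norm"
  )
}

#' Named reaction-norm constructors
#'
#' Convenience constructors for the norm shapes used throughout the package:
#' flat (environment-insensitive), linear, quadratic, logistic, and tabulated
#' (linear interpolation between measured points). The flat and linear shapes
#' admit closed-form composition with a Gaussian environment; the others are
#' composed by Monte Carlo.
#'
#' @param m Constant expected trait value (flat norm).
#' @param intercept,slope Coefficients of `h(x) = intercept + slope * x`.
#' @param a,b,c2 Coefficients of `h(x) = a + b*x + c2*x^2`.
#' @param lower,upper Asymptotes of the logistic norm.
#' @param midpoint,scale Location and steepness of the logistic transition;
#'   `h(x) = lower + (upper - lower) / (1 + exp(-(x - midpoint)/scale))`.
#' @param x,value Tabulated environmental values (strictly increasing) and
#'   the expected trait values measured at them.
#' @param file Optional path to a 2-column CSV (`x,value`, header required,
#'   dot decimal) to read a tabulated norm from.
#' @inheritParams reaction_norm
#' @return A `reaction_norm` object.
#' @name norm-constructors
NULL

#' @rdname norm-constructors
#' @export
norm_flat <- function(m, domain = c(-Inf, Inf), genotype = "g1") {
  check_number(m, "m")
  force(m)
  reaction_norm(function(x) rep_len(m, length(x)), domain, genotype,
                shape = "flat", params = list(m = m))
}

#' @rdname norm-constructors
#' @export
norm_linear <- function(intercept, slope, domain = c(-Inf, Inf), genotype = "g1") {
  check_number(intercept, "intercept"); check_number(slope, "slope")
  force(intercept); force(slope)
  reaction_norm(function(x) intercept + slope * x, domain, genotype,
                shape = if (slope == 0) "flat" else "linear",
                params = list(intercept = intercept, slope = slope))
}

#' @rdname norm-constructors
#' @export
norm_quadratic <- function(a, b, c2, domain = c(-Inf, Inf), genotype = "g1") {
  check_number(a, "a"); check_number(b, "b"); check_number(c2, "c2")
  force(a); force(b); force(c2)
  reaction_norm(function(x) a + b * x + c2 * x^2, domain, genotype,
                shape = if (c2 == 0) (if (b == 0) "flat" else "linear") else "general",
                params = list(a = a, b = b, c2 = c2))
}

#' @rdname norm-constructors
#' @export
norm_logistic <- function(lower, upper, midpoint, scale,
                          domain = c(-Inf, Inf), genotype = "g1") {
  check_number(lower, "lower"); check_number(upper, "upper")
  check_number(midpoint, "midpoint")
  check_number(scale, "scale", lower = 0, strict_lower = TRUE)
  force(lower); force(upper); force(midpoint); force(scale)
  reaction_norm(
    function(x) lower + (upper - lower) / (1 + exp(-(x - midpoint) / scale)),
    domain, genotype, shape = "monotone",
    params = list(lower = lower, upper = upper, midpoint = midpoint, scale = scale)
  )
}

#' @rdname norm-constructors
#' @export
norm_tabulated <- function(x, value = NULL, genotype = "g1", file = NULL) {
  if (!is.null(file)) {
    tab <- readr::read_csv(file, col_types = readr::cols(
      x = readr::col_double(), value = readr::col_double()
    ))
    x <- tab$x; value <- tab$value
  } else if (is.data.frame(x)) {
    if (!all(c("x", "value") %in% names(x))) {
      abort_validation("Tabulated norm data frame needs columns `x` and `value`.")
    }
    value <- x$value; x <- x$x
  }
  if (length(x) < 2L || any(is.na(x)) || any(is.na(value)) ||
      any(diff(x) <= 0) || length(x) != length(value)) {
    abort_validation(
      "Tabulated norm needs >= 2 rows with strictly increasing `x` and finite `value`.")
  }
  xs <- as.numeric(x); vs <- as.numeric(value)
  # extrapolation outside the tabulated range is a domain error, not clamping:
  # a norm is only trusted over the environmental range it was measured on
  h <- approxfun(xs, vs, method = "linear", rule = 1)
  reaction_norm(h, domain = range(xs), genotype = genotype, shape = "general",
                params = list(n_points = length(xs)))
}

#' Evaluate a reaction norm
#'
#' Returns the expected trait value `h(x)` for each environmental value `x`.
#' Values outside the norm's domain raise a domain error naming the interval.
#'
#' @param norm A [reaction_norm()] object.
#' @param x Numeric vector of environmental values.
#' @return Numeric vector of expected trait values.
#' @examples
#' eval_norm(norm_flat(3), c(0.2, 0.9))
#' eval_norm(norm_linear(0, 2), 1)
#' @export
eval_norm <- function(norm, x) {
  stopifnot(inherits(norm, "reaction_norm"))
  if (!is.numeric(x) || anyNA(x)) abort_validation("`x` must be numeric without NA.")
  bad <- x < norm$domain[1] | x > norm$domain[2]
  if (any(bad)) {
    abort_domain(sprintf(
      "Environmental value %s outside the norm's domain [%s, %s] (genotype %s).",
      format(x[which(bad)[1]]), format(norm$domain[1]), format(norm$domain[2]),
      norm$genotype
    ))
  }
  y <- norm$h(x)
  if (!is.numeric(y) || length(y) != length(x) || any(!is.finite(y))) {
    abort_validation("Reaction norm returned non-finite or mis-shaped values.")
  }
  y
}

#' Expected shift in trait value between two environments
#'
#' The difference `E(y | x2) - E(y | x1) = h(x2) - h(x1)`, the amount by which
#' the original study's confidence interval is shifted when the environments
#' of both studies are known. Antisymmetric in its arguments; identically zero
#' for a flat norm.
#'
#' @inheritParams eval_norm
#' @param x1,x2 Environmental values of the original and the replicate study.
#' @return Numeric vector of trait differences.
#' @export
expected_shift <- function(norm, x1, x2) {
  eval_norm(norm, x2) - eval_norm(norm, x1)
}

#' @export
print.reaction_norm <- function(x, ...) {
  cat(sprintf("<reaction_norm> genotype %s, shape %s, domain [%s, %s]\n",
              x$genotype, x$shape, format(x$domain[1]), format(x$domain[2])))
  if (length(x$params)) {
    cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                           collapse = ", "), "\n")
  }
  invisible(x)
}
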