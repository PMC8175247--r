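# Shared validation, seeding and small-sample statistics helpers.

abort_domain <- function(message, ...) {
  abort(message, class = "reactnorm_domain_error", ...)
}

abort_validation <- function(message, ...) {
  abort(message, class = "reactnorm_validation_error", ...)
}

abort_structural <- function(message, ...) {
  abort(message, class = "reactnorm_structural_error", ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x))) {
    abort_validation(sprintf("`%s` must be a single finite number.", name))
  }
  if (is.na(x)) return(invisible(x))
  if (x < lower || x > upper || (strict_lower && x == lower)) {
    abort_validation(sprintf(
      "`%s` must be in %s%s, %s]; got %s.",
      name, if (strict_lower) "(" else "[", format(lower), format(upper), format(x)
    ))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x %% 1 != 0 || x < lower) {
    abort_validation(sprintf("`%s` must be an integer >= %d.", name, lower))
  }
  invisible(as.integer(x))
}

check_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed %% 1 != 0) {
    abort_validation("`seed` must be a single integer (explicit seeding is required).")
  }
  as.integer(seed %% 2147483647)
}

# Deterministic substream derivation: every lab (and auxiliary stream) gets its
# own seed derived from the run seed. Products stay below 2^53 so arithmetic
# is exact in doubles; results stay below 2^31 for set.seed().
substream_seed <- function(seed, index, stream = 0L) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271 + as.numeric(index) * 65537 + as.numeric(stream) * 257) %%
               2147483647)
}

# Wilson score interval for a binomial proportion (no continuity correction).
wilson_ci <- function(successes, n, level = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n)
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

z_from_confidence <- function(confidence) {
  check_number(confidence, "confidence", lower = 0, upper = 1, strict_lower = TRUE)
  if (confidence >= 1) abort_validation("`confidence` must be in (0, 1).")
  qnorm(1 - (1 - confidence) / 2)
}
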