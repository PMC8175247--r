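# Replication-success criteria: naive CI inclusion, the shifted-CI rule for
# known study environments, and the tail-product rule for a known environment
# distribution; plus reproducibility rates over collections of study pairs.

assessment_tibble <- function(criterion, success, z = NA_real_, L = NA_real_,
                              lower = NA_real_, upper = NA_real_,
                              shift = NA_real_, product = NA_real_) {
  tibble::tibble(criterion = criterion, success = success, z = z, L = L,
                 lower = lower, upper = upper, shift = shift, product = product)
}

as_study_df <- function(x, name, cols) {
  if (is.list(x) && !is.data.frame(x)) x <- tibble::as_tibble(x[cols[cols %in% names(x)]])
  if (!is.data.frame(x)) abort_validation(sprintf("`%s` must be a data frame.", name))
  miss <- setdiff(cols, names(x))
  if (length(miss)) {
    abort_validation(sprintf("`%s` is missing column(s) %s.",
                             name, paste(miss, collapse = ", ")))
  }
  tibble::as_tibble(x)
}

#' Naive replication criterion
#'
#' A replicate study succeeds if its mean estimate falls strictly within the
#' original study's confidence interval `mean_effect +/- z * se`. Boundary
#' hits count as failures (the inequalities are strict).
#'
#' @param original,replicate Data frames (or named lists) of study results;
#'   `original` needs `mean_effect` and `se`, `replicate` needs
#'   `mean_effect`. Rows are paired (single rows are recycled).
#' @param z Confidence multiplier (default 1.96, two-sided 95%).
#' @return A tibble of assessments, one row per pair: `criterion`,
#'   `success`, `z`, `lower`, `upper`, and `shift`/`product` where
#'   applicable.
#' @examples
#' assess_naive(list(mean_effect = 0, se = 1), list(mean_effect = 1.9))
#' @export
assess_naive <- function(original, replicate, z = 1.96) {
  check_number(z, "z", lower = 0, strict_lower = TRUE)
  original <- as_study_df(original, "original", c("mean_effect", "se"))
  replicate <- as_study_df(replicate, "replicate", "mean_effect")
  if (any(!is.finite(original$se)) || any(original$se <= 0)) {
    abort_validation("Degenerate standard error: `original$se` must be > 0.")
  }
  n <- max(nrow(original), nrow(replicate))
  o <- original[rep_len(seq_len(nrow(original)), n), ]
  r <- replicate[rep_len(seq_len(nrow(replicate)), n), ]
  lower <- o$mean_effect - z * o$se
  upper <- o$mean_effect + z * o$se
  assessment_tibble("naive", r$mean_effect > lower & r$mean_effect < upper,
                    z = z, lower = lower, upper = upper, shift = 0)
}

#' Shifted-confidence-interval replication criterion
#'
#' When the reaction norm and both studies' environmental values are known,
#' the original study's confidence interval is shifted by the expected trait
#' difference `h(x2) - h(x1)` before checking whether the replicate's mean
#' falls inside it. With a flat norm the shift is zero and the criterion
#' reduces exactly to [assess_naive()].
#'
#' @inheritParams assess_naive
#' @param norm The shared [reaction_norm()] of the genotype under study.
#' @return A tibble of assessments (see [assess_naive()]); `shift` records
#'   `h(x2) - h(x1)`.
#' @export
assess_shifted <- function(original, replicate, norm, z = 1.96) {
  check_number(z, "z", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(norm, "reaction_norm"))
  original <- as_study_df(original, "original", c("mean_effect", "se", "x"))
  replicate <- as_study_df(replicate, "replicate", c("mean_effect", "x"))
  if (anyNA(original$x) || anyNA(replicate$x)) {
    abort(
      paste("Environmental covariate `x` is unknown for at least one study;",
            "use assess_naive() or assess_tail_product() instead."),
      class = "reactnorm_missing_covariate_error"
    )
  }
  if (any(!is.finite(original$se)) || any(original$se <= 0)) {
    abort_validation("Degenerate standard error: `original$se` must be > 0.")
  }
  n <- max(nrow(original), nrow(replicate))
  o <- original[rep_len(seq_len(nrow(original)), n), ]
  r <- replicate[rep_len(seq_len(nrow(replicate)), n), ]
  shift <- expected_shift(norm, o$x, r$x)
  lower <- shift + o$mean_effect - z * o$se
  upper <- shift + o$mean_effect + z * o$se
  assessment_tibble("shifted_ci", r$mean_effect > lower & r$mean_effect < upper,
                    z = z, lower = lower, upper = upper, shift = shift)
}

#' Tail-product replication criterion
#'
#' When only the distribution of expected trait values is known (not the
#' studies' environments), replication succeeds if the product of the two
#' studies' tail probabilities exceeds a critical value `L`. For each mean
#' independently the tail is taken on the side away from the distribution's
#' first moment `M1`: upper tail for a mean above `M1`, lower tail below. A
#' mean exactly at `M1` contributes 0.5 for the continuous symmetric
#' closed-form representation; for empirical samples the empirical upper-tail
#' mass at `M1` is used (no smoothing), and for a point mass the contribution
#' is 1.
#'
#' @param y1_bar,y2_bar Observed means of the original and replicate study
#'   (vectors are paired).
#' @param dist A `trait_dist` for the expected trait values.
#' @param L Critical product threshold in (0, 1); default `0.0025 = 0.05^2`,
#'   i.e. each study may sit at its two-sided 5% tail.
#' @param allow_small_sample Empirical distributions with fewer than 1000
#'   samples give imprecise tails and are rejected unless this is `TRUE`.
#' @return A tibble of assessments with the `product` column filled.
#' @examples
#' assess_tail_product(1.0, -0.5, trait_gaussian(0, 1))
#' @export
assess_tail_product <- function(y1_bar, y2_bar, dist, L = 0.0025,
                                allow_small_sample = FALSE) {
  stopifnot(inherits(dist, "trait_dist"))
  check_number(L, "L", lower = 0, upper = 1, strict_lower = TRUE)
  if (L >= 1) abort_validation("`L` must be in (0, 1).")
  if (!is.numeric(y1_bar) || !is.numeric(y2_bar) || anyNA(y1_bar) || anyNA(y2_bar)) {
    abort_validation("`y1_bar` and `y2_bar` must be numeric without NA.")
  }
  if (dist$representation == "empirical" && dist$sample_size < 1000 &&
      !allow_small_sample) {
    abort(
      sprintf(paste("Empirical trait distribution has only %d samples;",
                    "tail estimates are imprecise. Pass allow_small_sample = TRUE",
                    "to override."), dist$sample_size),
      class = "reactnorm_precision_error"
    )
  }
  n <- max(length(y1_bar), length(y2_bar))
  y1 <- rep_len(y1_bar, n); y2 <- rep_len(y2_bar, n)
  p1 <- outward_tail(dist, y1)
  p2 <- outward_tail(dist, y2)
  product <- p1 * p2
  assessment_tibble("tail_product", product > L, L = L, product = product)
}

# tail mass on the side away from M1; the M1 reference point decides the side
outward_tail <- function(dist, y) {
  M1 <- m1(dist)
  out <- numeric(length(y))
  up <- y > M1; lo <- y < M1; at <- y == M1
  if (any(up)) out[up] <- tail_prob(dist, y[up], "upper")
  if (any(lo)) out[lo] <- tail_prob(dist, y[lo], "lower")
  if (any(at)) {
    out[at] <- switch(dist$representation,
      gaussian = 0.5,
      pointmass = 1,
      empirical = tail_prob(dist, y[at], "upper")
    )
  }
  out
}

#' Reproducibility rate over a collection of study pairs
#'
#' Applies one replication criterion to each (original, replicate) pair and
#' reports the empirical success rate with a Wilson score confidence
#' interval.
#'
#' @param originals,replicates Data frames of paired study results (row `i`
#'   of each forms pair `i`).
#' @param criterion `"naive"`, `"shifted_ci"` or `"tail_product"`.
#' @param z,L,norm,dist Criterion parameters passed through to the
#'   corresponding `assess_*()` function.
#' @param conf_level Confidence level of the Wilson interval.
#' @param ... Further arguments passed to the assessor.
#' @return A one-row tibble: `criterion`, `n_pairs`, `successes`, `rate`,
#'   `conf.low`, `conf.high`.
#' @export
reproducibility_rate <- function(originals, replicates,
                                 criterion = c("naive", "shifted_ci", "tail_product"),
                                 z = 1.96, L = 0.0025, norm = NULL, dist = NULL,
                                 conf_level = 0.95, ...) {
  criterion <- match.arg(criterion)
  if (is.null(originals) || !nrow(tibble::as_tibble(originals))) {
    abort_structural("`originals` must contain at least one study pair.")
  }
  assessments <- switch(criterion,
    naive = assess_naive(originals, replicates, z = z),
    shifted_ci = {
      if (is.null(norm)) abort_validation("`norm` is required for the shifted criterion.")
      assess_shifted(originals, replicates, norm, z = z)
    },
    tail_product = {
      if (is.null(dist)) abort_validation("`dist` is required for the tail-product criterion.")
      o <- as_study_df(originals, "originals", "mean_effect")
      r <- as_study_df(replicates, "replicates", "mean_effect")
      assess_tail_product(o$mean_effect, r$mean_effect, dist, L = L, ...)
    }
  )
  k <- sum(assessments$success)
  n <- nrow(assessments)
  ci <- wilson_ci(k, n, conf_level)
  tibble::tibble(criterion = criterion, n_pairs = n, successes = k,
                 rate = k / n, conf.low = ci[["lower"]], conf.high = ci[["upper"]])
}
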