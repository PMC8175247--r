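#' Specify a multi-laboratory study design
#'
#' Describes a balanced two-arm (control/treatment) experiment replicated
#' across laboratories. Each lab experiences one value of the dominating
#' environmental factor: under `"standardized"` designs every lab sits at the
#' environment distribution's mean; under `"heterogenized"` designs each lab
#' draws its own value. On top of the dominating factor each lab receives a
#' Gaussian aggregate of small-effect factors (`small_effect_sd`) as a latent
#' baseline offset, and each animal independent within-lab noise
#' (`within_noise_sd`). The treatment effect is `delta0 + delta1 * x`, so
#' `delta1 != 0` makes the effect size environment-dependent — the mechanism
#' by which GxE enters between-lab effect variation (additive lab offsets
#' cancel in the within-lab contrast).
#'
#' @param n_labs Number of laboratories (>= 1).
#' @param n_per_arm Animals per arm per lab (>= 2).
#' @param genotypes A [reaction_norm()] or list of them (one per genotype).
#' @param standardization `"heterogenized"` or `"standardized"`.
#' @param within_noise_sd Within-lab residual SD (trait units, >= 0).
#' @param small_effect_sd SD of the between-lab Gaussian aggregate of
#'   small-effect factors (trait units, >= 0).
#' @param delta0 Baseline treatment effect (trait units).
#' @param delta1 Slope of the treatment effect per unit of the dominating
#'   environmental factor (trait units per environment unit).
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_labs, n_per_arm, genotypes,
                         standardization = c("heterogenized", "standardized"),
                         within_noise_sd = 1, small_effect_sd = 0,
                         delta0 = 0, delta1 = 0) {
  standardization <- match.arg(standardization)
  n_labs <- check_count(n_labs, "n_labs", lower = 1L)
  n_per_arm <- check_count(n_per_arm, "n_per_arm", lower = 2L)
  check_number(within_noise_sd, "within_noise_sd", lower = 0)
  check_number(small_effect_sd, "small_effect_sd", lower = 0)
  check_number(delta0, "delta0"); check_number(delta1, "delta1")
  if (inherits(genotypes, "reaction_norm")) genotypes <- list(genotypes)
  if (!length(genotypes) ||
      !all(vapply(genotypes, inherits, logical(1), "reaction_norm"))) {
    abort_validation("`genotypes` must be one or more reaction_norm objects.")
  }
  labels <- vapply(genotypes, `[[`, character(1), "genotype")
  if (anyDuplicated(labels)) abort_validation("Genotype labels must be unique.")
  names(genotypes) <- labels
  structure(
    list(n_labs = n_labs, n_per_arm = n_per_arm, genotypes = genotypes,
         standardization = standardization, within_noise_sd = within_noise_sd,
         small_effect_sd = small_effect_sd, delta0 = delta0, delta1 = delta1),
    class = "study_design"
  )
}

#' Simulate a multi-laboratory experiment
#'
#' Generates per-animal records under the generative model
#' \deqn{y = h_g(x_{lab}) + u_{lab} + 1[\mathrm{treatment}](\delta_0 + \delta_1 x_{lab}) + \epsilon,}
#' with `u_lab ~ N(0, small_effect_sd^2)` shared by all animals in a lab and
#' `eps ~ N(0, within_noise_sd^2)` independent per animal. Randomness flows
#' from the single `seed` through a per-lab substream (lab index, then animal
#' order within lab), so identical inputs reproduce identical records.
#'
#' @param design A [study_design()].
#' @param env An environment distribution for the dominating factor.
#' @param seed Integer seed.
#' @return A tibble with columns `lab_id`, `genotype`, `arm`, `x`, `u`, `y`
#'   and attributes `seed` and `design`.
#' @export
simulate_multilab <- function(design, env, seed) {
  stopifnot(inherits(design, "study_design"), inherits(env, "environment_dist"))
  seed <- check_seed(seed)
  arms <- c("control", "treatment")
  labs <- purrr::map(seq_len(design$n_labs), function(j) {
    withr::with_seed(substream_seed(seed, j), {
      x <- if (design$standardization == "standardized") env$mean
           else env$sampler(1)
      for (g in design$genotypes) {
        if (x < g$domain[1] || x > g$domain[2]) {
          abort_domain(sprintf(
            "Lab %d drew environmental value %s outside the domain [%s, %s] of genotype %s.",
            j, format(x), format(g$domain[1]), format(g$domain[2]), g$genotype))
        }
      }
      # scale a standard normal rather than rnorm(1, 0, sd): rnorm consumes no
      # deviate when sd = 0, which would desynchronise the per-lab stream
      # between otherwise identical designs
      u <- design$small_effect_sd * rnorm(1)
      cells <- tidyr::expand_grid(
        genotype = names(design$genotypes), arm = arms
      )
      purrr::pmap_dfr(cells, function(genotype, arm) {
        g <- design$genotypes[[genotype]]
        eps <- design$within_noise_sd * rnorm(design$n_per_arm)
        effect <- if (arm == "treatment") design$delta0 + design$delta1 * x else 0
        tibble::tibble(
          lab_id = j, genotype = genotype, arm = arm, x = x, u = u,
          y = eval_norm(g, x) + u + effect + eps
        )
      })
    })
  })
  out <- dplyr::bind_rows(labs)
  attr(out, "seed") <- seed
  attr(out, "design") <- design
  out
}

#' Summarise a multi-lab dataset into per-lab study results
#'
#' For each laboratory and genotype, computes the treatment-minus-control
#' mean effect, the pooled within-cell variance `s^2`, and the standard error
#' `sqrt(s^2 (1/n1 + 1/n2))`. Every (lab, genotype, arm) cell must hold at
#' least two animals.
#'
#' @param data A tibble as returned by [simulate_multilab()] (columns
#'   `lab_id`, `genotype`, `arm`, `x`, `y`).
#' @param allow_degenerate If `FALSE` (default), a pooled variance of zero is
#'   an error (the standard error is undefined as a yardstick); set `TRUE`
#'   only for deliberately noise-free checks.
#' @return A tibble of study results: `lab_id`, `genotype`, `mean_effect`,
#'   `se`, `n1`, `n2`, `x`, `s2`.
#' @export
summarize_labs <- function(data, allow_degenerate = FALSE) {
  need <- c("lab_id", "genotype", "arm", "x", "y")
  if (!all(need %in% names(data))) {
    abort_structural(sprintf("`data` must have columns %s.",
                             paste(need, collapse = ", ")))
  }
  cells <- data |>
    dplyr::group_by(.data$lab_id, .data$genotype, .data$arm) |>
    dplyr::summarise(n = dplyr::n(), m = mean(.data$y), v = var(.data$y),
                     x = .data$x[1], .groups = "drop")
  full <- tidyr::expand_grid(
    lab_id = unique(data$lab_id), genotype = unique(data$genotype),
    arm = c("control", "treatment")
  )
  missing <- dplyr::anti_join(full, cells, by = c("lab_id", "genotype", "arm"))
  small <- dplyr::filter(cells, .data$n < 2L)
  if (nrow(missing) || nrow(small)) {
    bad <- dplyr::bind_rows(missing[0 + seq_len(min(1, nrow(missing))), ],
                            small[0 + seq_len(min(1, nrow(small))), c("lab_id", "genotype", "arm")])
    abort_structural(sprintf(
      "Cell (lab %s, genotype %s, arm %s) is empty or has fewer than 2 animals.",
      bad$lab_id[1], bad$genotype[1], bad$arm[1]))
  }
  out <- cells |>
    tidyr::pivot_wider(names_from = "arm", values_from = c("n", "m", "v")) |>
    dplyr::mutate(
      mean_effect = .data$m_treatment - .data$m_control,
      n1 = .data$n_treatment, n2 = .data$n_control,
      s2 = ((.data$n1 - 1) * .data$v_treatment + (.data$n2 - 1) * .data$v_control) /
        (.data$n1 + .data$n2 - 2),
      se = sqrt(.data$s2 * (1 / .data$n1 + 1 / .data$n2))
    ) |>
    dplyr::select("lab_id", "genotype", "mean_effect", "se", "n1", "n2", "x", "s2") |>
    dplyr::arrange(.data$lab_id, .data$genotype)
  if (!allow_degenerate && any(out$se == 0)) {
    bad <- out[out$se == 0, ][1, ]
    abort_validation(sprintf(
      "Degenerate standard error (pooled variance 0) for lab %s, genotype %s; all values identical.",
      bad$lab_id, bad$genotype))
  }
  out
}

#' Gradient fixture: studies sorted along an environmental gradient
#'
#' Builds the hypothetical scenario of a collection of studies whose effect
#' size varies linearly along an environmental gradient (by default an
#' ambient-temperature range): study `i` sits at an evenly spaced value
#' `x_i`, its true effect is `delta0 + delta1 * x_i`, and its observed mean
#' effect is drawn Gaussian around the truth with SD `se_per_study`.
#'
#' @param n_studies Number of studies (>= 3; default 25).
#' @param x_range Environmental gradient interval (default `c(18, 30)`,
#'   degrees Celsius).
#' @param delta0 Intercept of the true effect (trait units).
#' @param delta1 Slope of the true effect per environment unit.
#' @param se_per_study Standard error of each study's mean effect (> 0).
#' @param n_per_arm Nominal per-arm sample size recorded in the results.
#' @param seed Integer seed.
#' @return A tibble of study results sorted by `x` (same columns as
#'   [summarize_labs()]).
#' @export
make_gradient_fixture <- function(n_studies = 25, x_range = c(18, 30),
                                  delta0 = -4.8, delta1 = 0.2,
                                  se_per_study = 0.3, n_per_arm = 10, seed) {
  n_studies <- check_count(n_studies, "n_studies", lower = 3L)
  check_number(se_per_study, "se_per_study", lower = 0, strict_lower = TRUE)
  n_per_arm <- check_count(n_per_arm, "n_per_arm", lower = 2L)
  if (!is.numeric(x_range) || length(x_range) != 2L || x_range[1] >= x_range[2]) {
    abort_validation("`x_range` must be an interval c(lo, hi) with lo < hi.")
  }
  seed <- check_seed(seed)
  x <- seq(x_range[1], x_range[2], length.out = n_studies)
  true_effect <- delta0 + delta1 * x
  observed <- withr::with_seed(seed, rnorm(n_studies, true_effect, se_per_study))
  tibble::tibble(
    lab_id = seq_len(n_studies), genotype = "g1",
    mean_effect = observed, se = se_per_study,
    n1 = n_per_arm, n2 = n_per_arm, x = x,
    s2 = se_per_study^2 / (1 / n_per_arm + 1 / n_per_arm)
  )
}
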