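# Shared generators for property-style tests. All randomness is drawn inside
# withr::with_seed so tests are deterministic.

# a random norm of random shape over a wide domain
random_norm <- function() {
  shape <- sample(c("flat", "linear", "quadratic", "logistic"), 1)
  switch(shape,
    flat = norm_flat(runif(1, -5, 5)),
    linear = norm_linear(runif(1, -5, 5), runif(1, -3, 3)),
    quadratic = norm_quadratic(runif(1, -2, 2), runif(1, -2, 2), runif(1, -1, 1)),
    logistic = norm_logistic(runif(1, -3, 0), runif(1, 0.5, 3),
                             runif(1, -1, 1), runif(1, 0.2, 2))
  )
}

random_flat_norm <- function() norm_flat(runif(1, -5, 5))

# one-row study tibbles for the assessors
study_row <- function(mean_effect, se = 1, x = NA_real_, n = 10) {
  tibble::tibble(mean_effect = mean_effect, se = se, x = x,
                 n1 = n, n2 = n, s2 = se^2 / (2 / n))
}

flat_design <- function(n_labs = 10, n_per_arm = 5, ...) {
  study_design(n_labs, n_per_arm, norm_flat(0), ...)
}
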