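test_that("naive criterion is strict interval inclusion", {
  orig <- study_row(0, se = 1)
  expect_true(assess_naive(orig, study_row(1.9))$success)
  expect_false(assess_naive(orig, study_row(2.0))$success)
  # a boundary hit is a failure: the inequalities are strict
  expect_false(assess_naive(orig, study_row(1.96))$success)
  a <- assess_naive(orig, study_row(1))
  expect_equal(c(a$lower, a$upper), c(-1.96, 1.96))
  expect_error(assess_naive(study_row(0, se = 0), study_row(0)),
               class = "reactnorm_validation_error")
})

test_that("shifted criterion moves the original interval by the expected trait difference", {
  n <- norm_linear(0, 2)
  orig <- study_row(0, se = 1, x = 0)
  # shift = h(1) - h(0) = 2: interval becomes (0.04, 3.96)
  a <- assess_shifted(orig, study_row(2.0, x = 1), n)
  expect_true(a$success)
  expect_equal(a$shift, 2)
  expect_equal(c(a$lower, a$upper), c(0.04, 3.96))
  expect_false(assess_shifted(orig, study_row(0.0, x = 1), n)$success)

  expect_error(assess_shifted(orig, study_row(1, x = NA), n),
               class = "reactnorm_missing_covariate_error")
})

test_that("with a flat norm the shifted criterion reduces exactly to the naive one", {
  withr::with_seed(123, {
    for (i in 1:200) {
      n <- random_flat_norm()
      orig <- study_row(runif(1, -5, 5), se = runif(1, 0.1, 3), x = runif(1, -3, 3))
      repl <- study_row(runif(1, -8, 8), x = runif(1, -3, 3))
      z <- runif(1, 0.5, 3)
      expect_identical(assess_shifted(orig, repl, n, z)$success,
                       assess_naive(orig, repl, z)$success)
    }
  })
})

test_that("assessments are equivariant under a common trait-scale shift", {
  withr::with_seed(31, {
    for (i in 1:50) {
      c0 <- runif(1, -10, 10)
      n <- norm_linear(1, 2)
      n_shifted <- norm_linear(1 + c0, 2)
      y1 <- runif(1, -3, 3); y2 <- runif(1, -3, 3)
      x1 <- runif(1, -2, 2); x2 <- runif(1, -2, 2)
      a <- assess_shifted(study_row(y1, 1, x1), study_row(y2, x = x2), n)
      b <- assess_shifted(study_row(y1 + c0, 1, x1), study_row(y2 + c0, x = x2),
                          n_shifted)
      expect_identical(a$success, b$success)
      expect_equal(b$lower - a$lower, c0)
    }
  })
})

test_that("tail product attains its symmetric maximum 0.25 at the first moment", {
  a <- assess_tail_product(0, 0, trait_gaussian(0, 1), L = 0.2)
  expect_equal(a$product, 0.25)
  expect_true(a$success)
  expect_false(assess_tail_product(0, 0, trait_gaussian(0, 1), L = 0.25)$success)
})

test_that("tail product matches the Gaussian CDF oracle", {
  # quadrature oracle for the two tail masses
  up <- integrate(dnorm, 1.0, Inf, rel.tol = 1e-13)$value
  lo <- integrate(dnorm, -Inf, -0.5, rel.tol = 1e-13)$value
  a <- assess_tail_product(1.0, -0.5, trait_gaussian(0, 1))
  expect_equal(a$product, up * lo, tolerance = 1e-10)
  expect_equal(a$product, 0.0490, tolerance = 1e-3)

  # a far-out original drives the product below any practical threshold
  far <- assess_tail_product(5, 0, trait_gaussian(0, 1), L = 1e-4)
  expect_false(far$success)
  expect_equal(far$product, pnorm(5, lower.tail = FALSE) * 0.5, tolerance = 1e-12)
  expect_lt(far$product, 1e-4)
})

test_that("tail sides are chosen independently per mean, away from M1", {
  d <- trait_gaussian(2, 1)
  a <- assess_tail_product(3, 1, d, L = 1e-6)
  expect_equal(a$product, pnorm(3, 2, 1, lower.tail = FALSE) * pnorm(1, 2, 1))
  # one mean exactly at M1 contributes 0.5 for the closed-form representation
  b <- assess_tail_product(2, 3, d)
  expect_equal(b$product, 0.5 * pnorm(3, 2, 1, lower.tail = FALSE))
})

test_that("the product is bounded by 0.25 and non-increasing in |mean - M1|", {
  d <- trait_gaussian(0, 1)
  grid <- expand.grid(y1 = seq(-3, 3, by = 0.25), y2 = seq(-3, 3, by = 0.25))
  prods <- assess_tail_product(grid$y1, grid$y2, d, L = 1e-9)$product
  expect_true(all(prods <= 0.25))
  expect_equal(max(prods), 0.25)  # attained only at (0, 0)
  expect_equal(sum(prods == 0.25), 1L)

  along <- assess_tail_product(seq(0, 4, by = 0.1), 0.7, d, L = 1e-9)$product
  expect_true(all(diff(along) <= 0))
})

test_that("empirical distributions need 1000 samples unless overridden", {
  small <- trait_empirical(withr::with_seed(1, rnorm(100)))
  expect_error(assess_tail_product(0, 0, small),
               class = "reactnorm_precision_error")
  expect_silent(assess_tail_product(0, 0, small, allow_small_sample = TRUE))
  big <- trait_empirical(withr::with_seed(1, rnorm(2000)))
  a <- assess_tail_product(1, -0.5, big)
  expect_equal(a$product, mean(big$samples > 1) * mean(big$samples < -0.5))
})

test_that("reproducibility rate counts successes with a Wilson interval", {
  studies <- study_row(rep(1, 10), se = 1)
  r <- reproducibility_rate(studies, studies, "naive")
  expect_equal(r$rate, 1)
  expect_equal(r$n_pairs, 10)
  expect_lt(r$conf.low, 1)

  # noise-free simulated pairs with flat norms succeed under all criteria
  des <- study_design(4, 3, norm_flat(0), within_noise_sd = 1e-9, delta0 = 1)
  res <- summarize_labs(simulate_multilab(des, env_gaussian(0, 1), 5))
  o <- res[c(1, 2), ]; rp <- res[c(3, 4), ]
  expect_equal(reproducibility_rate(o, rp, "naive")$rate, 1)
  expect_equal(reproducibility_rate(o, rp, "shifted_ci", norm = norm_flat(0))$rate, 1)

  expect_error(reproducibility_rate(study_row(numeric(0)), study_row(numeric(0)), "naive"),
               class = "reactnorm_structural_error")
})

test_that("knowing the environment raises the replication rate when effects track it", {
  # original studies standardized at the environment mean, replicates drawn
  # across the environment: shifting by the known expected difference
  # conditions away the environmental displacement
  norm <- norm_linear(0, 1)
  delta1 <- 0  # effect itself flat; displacement acts through the baseline norm
  n_pairs <- 500
  withr::with_seed(77, {
    x1 <- rep(0, n_pairs)
    x2 <- rnorm(n_pairs, 0, 1)
    se1 <- 0.3
    y1 <- rnorm(n_pairs, eval_norm(norm, x1), se1)
    y2 <- rnorm(n_pairs, eval_norm(norm, x2), se1)
  })
  o <- tibble::tibble(mean_effect = y1, se = se1, x = x1)
  r <- tibble::tibble(mean_effect = y2, se = se1, x = x2)
  rate_naive <- reproducibility_rate(o, r, "naive")$rate
  rate_shift <- reproducibility_rate(o, r, "shifted_ci", norm = norm)$rate
  expect_gt(rate_shift, rate_naive)
  # the criterion widens by the original SE only, so with equally noisy
  # replicates the ideal success rate is P(|N(0, sqrt(2) SE)| < 1.96 SE)
  ideal <- 2 * pnorm(1.96 / sqrt(2)) - 1
  expect_lt(abs(rate_shift - ideal), 3 * sqrt(ideal * (1 - ideal) / n_pairs))
})
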