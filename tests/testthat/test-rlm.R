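test_that("the adjusted standard error follows its closed form", {
  expect_equal(rlm_se(1, 2, 2, 0), 1.0)
  expect_equal(rlm_se(4, 8, 8, 0.5), sqrt(2))
  expect_equal(rlm_se(0, 10, 10, 0.125), 0.5)  # pure GxE: sqrt(2 * 0.125)
  expect_error(rlm_se(-1, 2, 2, 0), class = "reactnorm_validation_error")
  expect_error(rlm_se(1, 1, 2, 0), class = "reactnorm_validation_error")
})

test_that("with no GxE the adjusted SE reduces to the pooled SE to machine precision", {
  withr::with_seed(99, {
    s2 <- runif(1e4, 0, 10)
    n1 <- sample(2:50, 1e4, replace = TRUE)
    n2 <- sample(2:50, 1e4, replace = TRUE)
  })
  expect_identical(rlm_se(s2, n1, n2, 0), sqrt(s2 * (1 / n1 + 1 / n2)))
})

test_that("the adjusted SE is strictly increasing in the GxE component", {
  g <- seq(0, 3, by = 0.1)
  se <- vapply(g, function(v) rlm_se(2, 10, 12, v), numeric(1))
  expect_true(all(diff(se) > 0))
})

test_that("rlm_contrast widens intervals, nests them and shrinks the statistic", {
  study <- tibble::tibble(mean_effect = 1, s2 = 1, n1 = 2, n2 = 2)
  # no GxE: identical to the classical two-sample interval
  est0 <- rlm_contrast(study, 0)
  expect_equal(est0$se_adjusted, est0$se_classical)
  expect_equal(est0$conf.low, 1 - 1.96 * 1, tolerance = 1e-3)

  est <- rlm_contrast(study, 0.5)
  expect_equal(est$se_adjusted, sqrt(2))
  expect_equal(est$conf.low, 1 - qnorm(0.975) * sqrt(2))
  expect_equal(est$conf.high, 1 + qnorm(0.975) * sqrt(2))
  expect_equal(est$conf.low, -1.772, tolerance = 1e-3)
  expect_equal(est$conf.high, 3.772, tolerance = 1e-3)
  # strict nesting and attenuated evidence whenever s2_gxe > 0
  expect_lt(est$conf.low, est0$conf.low)
  expect_gt(est$conf.high, est0$conf.high)
  expect_lt(abs(est$statistic), abs(est0$statistic))

  # nesting holds across confidence levels
  for (conf in c(0.5, 0.8, 0.99)) {
    a <- rlm_contrast(study, 0.5, confidence = conf)
    b <- rlm_contrast(study, 0, confidence = conf)
    expect_lt(a$conf.low, b$conf.low)
    expect_gt(a$conf.high, b$conf.high)
  }
  expect_s3_class(tidy(est), "tbl_df")
  expect_equal(glance(est)$mean_widening, sqrt(2))
})

test_that("identical per-lab effects truncate the moment estimate at zero", {
  studies <- tibble::tibble(
    lab_id = 1:5, genotype = "g1", mean_effect = 2, se = 0.5,
    n1 = 10L, n2 = 10L, x = 0, s2 = 1.25
  )
  est <- estimate_gxe_variance(studies)
  expect_equal(est$s2_gxe, 0)
  expect_equal(est$between_var, 0)
  expect_equal(est$mean_sampling_var, 0.25)
})

test_that("fewer than three labs cannot identify the GxE component", {
  des <- study_design(2, 5, norm_flat(0))
  dat <- simulate_multilab(des, env_gaussian(0, 1), 1)
  expect_error(estimate_gxe_variance(dat),
               class = "reactnorm_insufficient_replication_error")
})

test_that("without environment-dependent effects the estimate concentrates near zero", {
  meds <- vapply(1:50, function(s) {
    des <- study_design(20, 10, norm_flat(0), within_noise_sd = 1,
                        small_effect_sd = 0.5, delta1 = 0)
    estimate_gxe_variance(simulate_multilab(des, env_gaussian(0, 1), s))$s2_gxe
  }, numeric(1))
  expect_lte(median(meds), 0.05)
})

test_that("the estimator recovers an injected between-lab effect variance", {
  # delta1 = 1, sd(X) = 1: between-lab effect variance 1, so s2_gxe = 0.5
  ests <- vapply(1:30, function(s) {
    des <- study_design(50, 20, norm_flat(0), within_noise_sd = 1, delta1 = 1)
    estimate_gxe_variance(simulate_multilab(des, env_gaussian(0, 1), s))$s2_gxe
  }, numeric(1))
  expect_gt(median(ests), 0.35)
  expect_lt(median(ests), 0.65)
})

test_that("coverage with zero GxE adjustment equals classical coverage", {
  des <- study_design(1, 10, norm_flat(0), within_noise_sd = 1, delta0 = 1)
  tab <- coverage_experiment(des, env_gaussian(0, 1), n_replicates = 200,
                             s2_gxe_used = 0, seed = 12)
  expect_equal(tab$coverage[tab$procedure == "rlm"],
               tab$coverage[tab$procedure == "classical"])
})

test_that("both procedures are nominal when effects do not depend on the environment", {
  # large arms so the Gaussian reference is adequate for the classical interval
  des <- study_design(1, 100, norm_flat(0), within_noise_sd = 1,
                      delta0 = 1, delta1 = 0)
  tab <- coverage_experiment(des, env_gaussian(0, 1), n_replicates = 500,
                             s2_gxe_used = "oracle", seed = 13)
  expect_equal(tab$s2_gxe, c(0, 0))  # oracle value under no GxE
  for (p in c("classical", "rlm")) {
    row <- tab[tab$procedure == p, ]
    expect_lte(row$conf.low, 0.95)
    expect_gte(row$conf.high, 0.95)
  }
})
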