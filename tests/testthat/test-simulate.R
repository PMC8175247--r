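test_that("the noise-free limit reproduces the base effect exactly", {
  des <- study_design(5, 3, norm_flat(2), within_noise_sd = 0,
                      small_effect_sd = 0, delta0 = 1.5, delta1 = 0)
  dat <- simulate_multilab(des, env_gaussian(0, 1), seed = 1)
  effects <- dat |>
    dplyr::group_by(lab_id) |>
    dplyr::summarise(d = mean(y[arm == "treatment"]) - mean(y[arm == "control"]))
  expect_equal(effects$d, rep(1.5, 5))
  # and propagates through summarisation
  res <- summarize_labs(dat, allow_degenerate = TRUE)
  expect_equal(res$mean_effect, rep(1.5, 5))
})

test_that("standardized designs share one dominating-factor value; heterogenized do not", {
  env <- env_gaussian(3, 1)
  std <- simulate_multilab(study_design(5, 3, norm_flat(0),
                                        standardization = "standardized"),
                           env, seed = 2)
  expect_equal(unique(std$x), 3)  # the environment's mean, every lab
  het <- simulate_multilab(study_design(5, 3, norm_flat(0),
                                        standardization = "heterogenized"),
                           env, seed = 2)
  expect_equal(length(unique(het$x)), 5)
})

test_that("record structure and within-lab constancy hold", {
  des <- study_design(4, 3, list(norm_linear(0, 1, genotype = "a"),
                                 norm_flat(1, genotype = "b")),
                      small_effect_sd = 1)
  dat <- simulate_multilab(des, env_gaussian(0, 1), seed = 5)
  expect_equal(nrow(dat), 4 * 2 * 3 * 2)  # labs x arms x per-arm x genotypes
  per_lab <- dat |>
    dplyr::group_by(lab_id) |>
    dplyr::summarise(nx = dplyr::n_distinct(x), nu = dplyr::n_distinct(u))
  expect_true(all(per_lab$nx == 1 & per_lab$nu == 1))
})

test_that("per-lab true effects have the variance the environment slope induces", {
  # delta0 = 0, delta1 = 1, X ~ N(0,1): per-lab effect = X, so mean 0, var 1
  des <- study_design(2000, 2, norm_flat(0), within_noise_sd = 0,
                      delta0 = 0, delta1 = 1)
  dat <- simulate_multilab(des, env_gaussian(0, 1), seed = 6)
  d <- summarize_labs(dat, allow_degenerate = TRUE)$mean_effect
  expect_lt(abs(mean(d)), 3 / sqrt(2000))
  expect_lt(abs(var(d) - 1), 3 * sqrt(2 / 1999))  # var of a sample variance
})

test_that("additive lab offsets cancel in the contrast; environment-dependent effects do not", {
  env <- env_gaussian(0, 1)
  base <- study_design(2000, 5, norm_flat(0), within_noise_sd = 1,
                       small_effect_sd = 0, delta1 = 0)
  with_u <- study_design(2000, 5, norm_flat(0), within_noise_sd = 1,
                         small_effect_sd = 3, delta1 = 0)
  v0 <- var(summarize_labs(simulate_multilab(base, env, 7))$mean_effect)
  vu <- var(summarize_labs(simulate_multilab(with_u, env, 7))$mean_effect)
  # u_lab enters both arms identically, so the effect variance is unchanged
  expect_identical(v0, vu)
  # sampling theory: var(mean_effect) = s2 (1/n1 + 1/n2) = 2/5 when delta1 = 0
  expect_equal(v0, 1 * (1 / 5 + 1 / 5), tolerance = 0.1)
  # an environment-dependent effect inflates it by delta1^2 var(X)
  slope <- study_design(2000, 5, norm_flat(0), within_noise_sd = 1, delta1 = 1)
  vs <- var(summarize_labs(simulate_multilab(slope, env, 7))$mean_effect)
  expect_equal(vs, 2 / 5 + 1, tolerance = 0.15)
  expect_gt(vs, v0)
})

test_that("with environment-dependent effects, standardization shrinks between-lab effect variance", {
  env <- env_gaussian(0, 1)
  mk <- function(stdz) study_design(2000, 5, norm_flat(0), within_noise_sd = 1,
                                    delta1 = 1, standardization = stdz)
  v_std <- var(summarize_labs(simulate_multilab(mk("standardized"), env, 8))$mean_effect)
  v_het <- var(summarize_labs(simulate_multilab(mk("heterogenized"), env, 8))$mean_effect)
  expect_lt(v_std, v_het)
})

test_that("simulation is seed-deterministic down to byte-identical CSV exports", {
  des <- study_design(6, 4, norm_linear(1, 0.5), small_effect_sd = 0.3, delta0 = 1)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_multilab_csv(simulate_multilab(des, env_gaussian(0, 1), 42), f1)
  write_multilab_csv(simulate_multilab(des, env_gaussian(0, 1), 42), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a different seed changes the records
  expect_false(identical(simulate_multilab(des, env_gaussian(0, 1), 42)$y,
                         simulate_multilab(des, env_gaussian(0, 1), 43)$y))
})

test_that("lab draws outside a genotype's domain are domain errors naming the lab", {
  des <- study_design(20, 2, norm_linear(0, 1, domain = c(-0.5, 0.5)))
  expect_error(simulate_multilab(des, env_gaussian(0, 1), seed = 3),
               class = "reactnorm_domain_error")
  expect_error(simulate_multilab(des, env_gaussian(0, 1), seed = 3), "Lab")
})

test_that("summarize_labs computes the pooled-variance standard error", {
  dat <- tibble::tibble(
    lab_id = 1L, genotype = "g1",
    arm = rep(c("control", "treatment"), each = 2),
    x = 0, u = 0, y = c(0, 2, 3, 5)
  )
  res <- summarize_labs(dat)
  expect_equal(res$mean_effect, 3)
  expect_equal(res$s2, 2)          # hand-pooled: ((1)2 + (1)2) / 2
  expect_equal(res$se, sqrt(2))    # sqrt(2 (1/2 + 1/2))
  expect_equal(res$n1, 2L)
  expect_equal(res$n2, 2L)
})

test_that("summarize_labs guards degenerate and ill-formed cells", {
  flat0 <- tibble::tibble(
    lab_id = 1L, genotype = "g1",
    arm = rep(c("control", "treatment"), each = 2),
    x = 0, u = 0, y = c(1, 1, 3, 3)
  )
  expect_error(summarize_labs(flat0), class = "reactnorm_validation_error")
  expect_equal(summarize_labs(flat0, allow_degenerate = TRUE)$mean_effect, 2)

  one_armed <- dplyr::filter(flat0, arm == "control")
  expect_error(summarize_labs(one_armed), class = "reactnorm_structural_error")
  expect_error(summarize_labs(flat0[c(1, 3, 4), ]),
               class = "reactnorm_structural_error")
})

test_that("gradient fixture spaces studies evenly and recovers its slope", {
  fx <- make_gradient_fixture(seed = 1)
  expect_equal(nrow(fx), 25)
  expect_equal(fx$x, seq(18, 30, length.out = 25))
  expect_true(!is.unsorted(fx$x))

  # flat gradient, vanishing noise: all effects collapse to delta0
  flat <- make_gradient_fixture(delta0 = 2, delta1 = 0, se_per_study = 1e-12, seed = 2)
  expect_equal(flat$mean_effect, rep(2, 25), tolerance = 1e-10)

  # least-squares recovery of the generating slope
  fx2 <- make_gradient_fixture(x_range = c(18, 30), delta0 = 0, delta1 = 1,
                               se_per_study = 0.1, seed = 3)
  fit <- lm(mean_effect ~ x, data = fx2)
  expect_lt(abs(coef(fit)[["x"]] - 1), 3 * summary(fit)$coefficients["x", "Std. Error"])
})

test_that("multi-lab CSV round-trips losslessly", {
  des <- study_design(3, 3, norm_flat(1), delta0 = 0.5)
  dat <- simulate_multilab(des, env_gaussian(0, 1), 13)
  f <- withr::local_tempfile(fileext = ".csv")
  write_multilab_csv(dat, f)
  back <- read_multilab_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(dat[names(back)]),
               ignore_attr = TRUE)
})
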