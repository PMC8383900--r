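test_that("the correlation solve reproduces the published model structure", {
  cal <- generator_calibration()
  S <- calibrate_predictor_corr(cal)
  expect_equal(diag(S), setNames(rep(1, 6), cohort_predictors))
  expect_equal(S, t(S))
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)

  beta <- cal$std_betas
  expect_lt(abs(drop(beta %*% S %*% beta) - cal$target_model_R^2), 1e-3)
  expect_lt(abs(drop(S %*% beta)[1] - cal$target_age_r), 0.02)
  expect_true(all(abs(diag(solve(S)) - cal$target_vifs) < 0.05))

  # independent VIF route: regress each latent on the others in a large
  # simulated draw with this correlation structure
  set.seed(99)
  Z <- matrix(rnorm(20000 * 6), 20000, 6) %*% chol(S)
  for (j in 1:6) {
    r2 <- summary(lm(Z[, j] ~ Z[, -j]))$r.squared
    expect_lt(abs(1 / (1 - r2) - cal$target_vifs[j]), 0.07)
  }
})

test_that("generated cohorts match the published marginals", {
  co <- ref_cohort()
  expect_identical(nrow(co), 3074L)
  expect_lt(abs(mean(co$age) - 64.1), 0.5)
  expect_true(all(co$ftd >= 0 & co$ftd <= 1))
  expect_true(all(co$age >= 50 & co$age <= 93))
  expect_equal(co$se, co$sphere + co$cylinder / 2)
  my <- co$se < -0.25
  expect_lt(abs(mean(co$se[my]) - (-2.16)), 0.15)
  expect_lt(abs(mean(co$sex == "female") - 0.564), 0.03)
  expect_error(generate_cohort(10), class = "CohortTooSmall")
})

test_that("the simulated design correlation converges to the solved matrix", {
  co <- ref_cohort()
  X <- sapply(cohort_predictors, function(nm) fundtess:::design_column(co[[nm]], nm))
  S <- calibrate_predictor_corr(generator_calibration())
  expect_lt(max(abs(cor(X) - S)), 0.03)
})

test_that("univariate screening matches closed forms and the normal equations", {
  co <- ref_cohort()
  std <- data.frame(x = as.numeric(scale(co$age)), ftd = as.numeric(scale(co$ftd)))
  scr <- univariate_screen(std, outcome = "ftd")
  expect_equal(scr$beta, cor(std$x, std$ftd), tolerance = 1e-12)

  set.seed(5)
  small <- data.frame(x = rnorm(20), ftd = rnorm(20))
  scr2 <- univariate_screen(small, outcome = "ftd")
  A <- cbind(1, small$x)
  bhat <- solve(t(A) %*% A, t(A) %*% small$ftd)  # normal-equations oracle
  expect_equal(scr2$b, bhat[2], tolerance = 1e-10)

  small$flat <- 1
  expect_error(univariate_screen(small, outcome = "ftd"),
               class = "ConstantPredictor")
})

test_that("stepwise selection prunes collinearity then insignificance", {
  co <- ref_cohort()
  co$al_dup <- fundtess:::with_local_seed(77, {
    co$axial_length + rnorm(nrow(co), 0, sd(co$axial_length) * sqrt(1 / 0.999^2 - 1))
  })
  expect_gt(cor(co$al_dup, co$axial_length), 0.998)
  rep <- multivariate_stepwise(co, c(cohort_predictors, "al_dup"))
  expect_lte(sum(c("axial_length", "al_dup") %in% rep$terms$predictor), 1)
  expect_true(any(grepl("^vif", rep$steps)))
  expect_true(all(rep$terms$vif <= 3))
  expect_true(all(rep$terms$p <= 0.05))
  expect_true(all(rep$terms$ci_lo <= rep$terms$b & rep$terms$b <= rep$terms$ci_hi))

  # reported VIFs equal the brute-force leave-one-out regressions
  X <- sapply(rep$terms$predictor, function(nm) fundtess:::design_column(co[[nm]], nm))
  for (j in seq_len(ncol(X))) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(rep$terms$vif[j], 1 / (1 - r2), tolerance = 1e-10)
  }

  noise2 <- data.frame(ftd = rnorm(100), a = rnorm(100), b = rnorm(100))
  expect_error(multivariate_stepwise(noise2, c("a", "b"), alpha = 1e-12),
               class = "EmptyModel")
})

test_that("recovered standardized coefficients land inside the Table-style CIs", {
  co <- ref_cohort()
  cal <- generator_calibration()
  rep <- multivariate_stepwise(co, cohort_predictors)
  tm <- rep$terms[match(cohort_predictors, rep$terms$predictor), ]
  # on this calibrated cohort every generating beta should be recovered
  # within +- 0.04 (roughly 2 standard errors at n = 3074)
  expect_true(all(abs(tm$beta - cal$std_betas) < 0.04))
  expect_lt(abs(rep$model_r - cal$target_model_R), 0.03)
})

test_that("stratified summaries partition the cohort with strict SE cut-offs", {
  co <- ref_cohort()
  st <- stratified_summaries(co)
  expect_identical(sum(st$age_groups$n), nrow(co))
  expect_identical(sum(st$refraction$n), nrow(co))
  expect_identical(sum(st$sex$n), nrow(co))
  expect_lt(st$anova_p, 0.001)
  expect_lt(st$t_p, 0.001)

  # an SE of exactly -0.25 D is emmetropic (strict inequalities)
  edge <- data.frame(age = rep(c(55, 65, 75), 20), sex = rep(c("male", "female"), 30),
                     se = rep(-0.25, 60), ftd = runif(60, 0, 0.3))
  st2 <- stratified_summaries(edge)
  expect_identical(st2$refraction$n[st2$refraction$class == "emmetropia"], 60L)
  expect_identical(st2$refraction$n[st2$refraction$class == "myopia"], 0L)
  expect_true(is.na(st2$refraction$ftd_mean[st2$refraction$class == "myopia"]))
})

test_that("cohort CSV IO round-trips with the fixed header", {
  co <- generate_cohort(60, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_identical(readLines(path, n = 1),
                   "age,sex,bmi,axial_length,ppa_area,sfct,sphere,cylinder,se,ftd")
  back <- read_cohort(path)
  expect_equal(back$ftd, co$ftd, tolerance = 1e-12)
  expect_identical(back$sex, co$sex)
})
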