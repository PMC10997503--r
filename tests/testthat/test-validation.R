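test_that("harrell_c matches hand-enumerated toy cases", {
  expect_equal(harrell_c(c(3, 2, 1),
                         data.frame(time = c(1, 2, 3), event = c(1, 1, 1))),
               1)
  # times (1,3,2), scores (2,1,0.5): 2 of 3 usable pairs concordant
  expect_equal(harrell_c(c(2, 1, 0.5),
                         data.frame(time = c(1, 3, 2), event = c(1, 1, 1))),
               2 / 3)
  # all scores tied -> 0.5 by the tie convention
  expect_equal(harrell_c(c(1, 1),
                         data.frame(time = c(1, 2), event = c(1, 1))),
               0.5)
  expect_error(harrell_c(1, data.frame(time = 1, event = 1)[0, ]),
               "length mismatch")
  # all censored: no usable pairs
  expect_error(harrell_c(c(1, 2),
                         data.frame(time = c(1, 2), event = c(0, 0))),
               "no usable pairs")
})

test_that("harrell_c equals the brute-force pair enumeration oracle", {
  set.seed(101)
  for (r in 1:6) {
    n <- sample(20:200, 1)
    score <- sample(round(rnorm(n), 1))       # induces score ties
    time <- sample(1:40, n, replace = TRUE)   # induces time ties
    event <- rbinom(n, 1, 0.6)
    if (sum(event) == 0) event[1] <- 1L
    out <- data.frame(time = time, event = event)
    expect_equal(harrell_c(score, out),
                 brute_harrell_c(score, time, event))
  }
})

test_that("reversing score signs maps C to 1 - C on tie-free data", {
  set.seed(5)
  n <- 150
  score <- rnorm(n)
  out <- data.frame(time = rexp(n, exp(0.8 * score) * 0.1) + runif(n, 0, 1e-6),
                    event = rbinom(n, 1, 0.7))
  out$event[1] <- 1L
  expect_equal(harrell_c(-score, out), 1 - harrell_c(score, out),
               tolerance = 1e-12)
})

test_that("calibration slope is 1 for the true score and 1/a for a scaled score", {
  set.seed(19)
  d <- sim_ph_data(4000, c(0.7, -0.7))
  cs <- calibration_slope(d$lp, d$outcomes)
  expect_lt(abs(cs$slope - 1), 3.5 * cs$se)
  expect_gt(cs$p_vs_one, 0.001)
  cs2 <- calibration_slope(2 * d$lp, d$outcomes)
  # scaling the score by a rescales the slope by exactly 1/a
  expect_equal(cs2$slope, cs$slope / 2, tolerance = 1e-7)
  expect_lt(abs(cs2$slope - 0.5), 3.5 * cs2$se)
  expect_error(calibration_slope(rep(1, 4000), d$outcomes), "constant")
})

test_that("coefficient equality test: exact match, 1-df reduction, type-I error", {
  d <- sim_ph_data(600, c(0.5, -0.5), seed = 23)
  fit <- fit_cox(d$outcomes, d$covariates)
  same <- coefficient_equality_test(fit, fit$coefficients)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # single coefficient: statistic equals the squared Wald z
  d1 <- sim_ph_data(300, c(0.5), seed = 29)
  f1 <- fit_cox(d1$outcomes, d1$covariates)
  ref <- c(x1 = 0.5)
  t1 <- coefficient_equality_test(f1, ref)
  z2 <- ((f1$coefficients[["x1"]] - 0.5) / sqrt(f1$covariance[1, 1]))^2
  expect_equal(t1$statistic, z2, tolerance = 1e-10)
  expect_error(coefficient_equality_test(f1, c(other = 0.5)), "names differ")
  # testing against the generating coefficients rejects at ~5%
  set.seed(33)
  rej <- mean(replicate(120, {
    dd <- sim_ph_data(700, c(0.5, -0.5))
    ff <- fit_cox(dd$outcomes, dd$covariates)
    coefficient_equality_test(ff, c(x1 = 0.5, x2 = -0.5))$p < 0.05
  }))
  expect_gt(rej, 0.005)
  expect_lt(rej, 0.13)
})

test_that("bootstrap optimism is reproducible and positive in an overfit regime", {
  # n = 30 with 8 covariates must overfit
  d <- sim_ph_data(30, rep(0.3, 8), censor = c(5, 50), seed = 61)
  b1 <- bootstrap_optimism(d$outcomes, d$covariates, B = 150, seed = 99)
  b2 <- bootstrap_optimism(d$outcomes, d$covariates, B = 150, seed = 99)
  expect_identical(b1, b2)
  expect_gt(b1$optimism, 0)
  expect_equal(b1$corrected_c, b1$apparent_c - b1$optimism)
  expect_lt(b1$slope_shrinkage, 1)
})

test_that("calibration curve degenerates to the marginal comparison with one bin", {
  set.seed(71)
  d <- sim_ph_data(600, c(0.6), censor = c(4, 30))
  fit <- fit_cox(d$outcomes, d$covariates)
  bs <- baseline_survival(fit)
  lp <- linear_predictor(fit, d$covariates)
  cc <- calibration_curve(lp, d$outcomes, bs, horizon = 3, bins = 1)
  expect_equal(nrow(cc), 1)
  km <- km_estimate(d$outcomes)
  expect_equal(cc$observed_km, survival_at(km, 3))
  expect_equal(cc$mean_predicted, mean(survival_at(bs, 3)^exp(lp)))
  expect_error(calibration_curve(lp, d$outcomes, bs, horizon = 1e3),
               "horizon")
})

test_that("calibration curve tracks the diagonal for a well-specified model", {
  set.seed(73)
  d <- sim_ph_data(3000, c(0.8, -0.4), censor = c(4, 30))
  fit <- fit_cox(d$outcomes, d$covariates)
  bs <- baseline_survival(fit)
  lp <- linear_predictor(fit, d$covariates)
  cc <- calibration_curve(lp, d$outcomes, bs, horizon = 3, bins = 8)
  expect_equal(nrow(cc), 8)
  sl <- coef(lm(observed_km ~ mean_predicted, data = cc))[2]
  expect_equal(unname(sl), 1, tolerance = 0.2)
  expect_true(all(abs(cc$observed_km - cc$mean_predicted) < 0.08))
})

test_that("a bin with no events by the horizon reports observed survival 1", {
  out <- data.frame(time = c(10, 11, 12, 13), event = c(0, 0, 0, 1))
  scores <- c(0.1, 0.2, 0.3, 0.4)
  bs <- structure(list(times = c(13), s0 = c(0.9)),
                  class = "baseline_survival")
  cc <- calibration_curve(scores, out, bs, horizon = 5, bins = 2)
  expect_equal(cc$observed_km, c(1, 1))
})

test_that("the full external validation battery runs and is internally consistent", {
  coh <- simulate_cohort(sim_config(n = 3000, seed = 47))
  v <- validate_pi(pi_coefficients("published_cog"), coh, endpoint = "rfs")
  expect_s3_class(v, "pi_validation")
  # scored with the generating model: slope near 1, useful discrimination
  expect_equal(v$calibration$slope, 1, tolerance = 3 * v$calibration$se)
  expect_gt(v$c_index, 0.6)
  expect_lt(v$c_index, 0.9)
  expect_gt(v$coefficient_test$p, 0.001)
  expect_equal(v$coefficient_test$df, 8)
  expect_equal(length(v$km_groups), 4)
  expect_output(print(v), "calibration slope")
})
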