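test_that("fit_cox recovers generating coefficients within 3 SE", {
  beta <- c(0.8, -0.5, 0.3)
  d <- sim_ph_data(4000, beta, seed = 21)
  fit <- fit_cox(d$outcomes, d$covariates)
  se <- sqrt(diag(fit$covariance))
  expect_true(all(abs(fit$coefficients - beta) < 3 * se))
  expect_true(fit$loglik >= fit$loglik_null)
  expect_true(isSymmetric(fit$covariance, tol = 1e-10))
  expect_true(all(eigen(fit$covariance, only.values = TRUE)$values > 0))
})

test_that("fit_cox contracts: no events, constant and collinear columns", {
  d <- sim_ph_data(50, c(0.5), seed = 3)
  out0 <- d$outcomes
  out0$event <- 0L
  expect_error(fit_cox(out0, d$covariates), "no events")
  xc <- d$covariates
  xc$flat <- 1
  expect_error(fit_cox(d$outcomes, xc), "constant covariate column: flat")
  xd <- d$covariates
  xd$dup <- 2 * xd$x1
  expect_error(fit_cox(d$outcomes, xd), "collinear")
})

test_that("Efron and Breslow agree exactly without tied event times", {
  d <- sim_ph_data(300, c(0.6, -0.4), seed = 5)
  stopifnot(!anyDuplicated(d$outcomes$time[d$outcomes$event == 1]))
  fe <- fit_cox(d$outcomes, d$covariates, "efron")
  fb <- fit_cox(d$outcomes, d$covariates, "breslow")
  expect_equal(fe$coefficients, fb$coefficients, tolerance = 1e-10)
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-10)
})

test_that("rescaling a covariate rescales its coefficient inversely", {
  d <- sim_ph_data(500, c(0.5, -0.3), seed = 8)
  f1 <- fit_cox(d$outcomes, d$covariates)
  x2 <- d$covariates
  x2$x1 <- x2$x1 * 10
  f2 <- fit_cox(d$outcomes, x2)
  expect_equal(f2$coefficients[["x1"]], f1$coefficients[["x1"]] / 10,
               tolerance = 1e-7)
  expect_equal(f2$coefficients[["x2"]], f1$coefficients[["x2"]],
               tolerance = 1e-7)
})

test_that("linear_predictor is the plain uncentered dot product", {
  cs <- coefficient_set("toy", c(a = 1, b = -1))
  expect_equal(linear_predictor(cs, c(a = 2, b = 3)), -1)
  expect_equal(linear_predictor(coefficient_set("z", c(a = 0, b = 0)),
                                c(a = 5, b = 7)), 0)
  d <- sim_ph_data(100, c(0.5, -0.2), seed = 2)
  fit <- fit_cox(d$outcomes, d$covariates)
  expect_equal(linear_predictor(fit, d$covariates),
               drop(as.matrix(d$covariates) %*% fit$coefficients))
  # consistency contract with score_pi
  expect_identical(linear_predictor(cs, c(a = 2, b = 3)),
                   score_pi(cs, c(a = 2, b = 3)))
})

test_that("baseline survival matches a known constant hazard", {
  # exponential baseline 0.05/y, null covariate effect:
  # s0(5) should be close to exp(-0.25) = 0.7788
  set.seed(31)
  n <- 5000
  x <- data.frame(x1 = rnorm(n))
  t_ev <- rexp(n, 0.05)
  t_c <- runif(n, 10, 40)
  out <- data.frame(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
  fit <- fit_cox(out, x)
  bs <- baseline_survival(fit)
  expect_equal(survival_at(bs, 5), exp(-0.25), tolerance = 0.02)
  expect_equal(survival_at(bs, 0), 1)
  expect_true(all(diff(bs$s0) <= 1e-12))
})

test_that("Schoenfeld residuals sum to zero and dfbeta tracks leave-one-out", {
  d <- sim_ph_data(50, c(0.5, -0.5), censor = c(2, 30), seed = 13)
  fit <- fit_cox(d$outcomes, d$covariates)
  dg <- ph_diagnostics(fit)
  expect_equal(colSums(dg$schoenfeld$raw), c(x1 = 0, x2 = 0),
               tolerance = 1e-8)
  expect_equal(nrow(dg$dfbeta), 50)
  # removing subject i shifts beta by about -dfbeta[i, ]
  for (i in c(4, 17, 32)) {
    refit <- fit_cox(d$outcomes[-i, ], d$covariates[-i, ])
    delta <- refit$coefficients - fit$coefficients
    expect_equal(unname(delta), unname(-dg$dfbeta[i, ]), tolerance = 0.35)
  }
})

test_that("PH slope test holds its nominal size under proportional hazards", {
  set.seed(77)
  rejections <- 0L
  reps <- 120
  for (r in seq_len(reps)) {
    d <- sim_ph_data(150, c(0.7), censor = c(2, 30))
    fit <- fit_cox(d$outcomes, d$covariates)
    dg <- ph_diagnostics(fit)
    if (dg$schoenfeld$table["x1", "p"] < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / reps, 0.005)
  expect_lt(rejections / reps, 0.13)
})

test_that("diagnostics need at least three events", {
  out <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0))
  x <- data.frame(x1 = c(0.1, -0.2, 0.4, 1))
  fit <- fit_cox(out, x)
  expect_error(ph_diagnostics(fit), "fewer than 3 events")
})

test_that("nested likelihood-ratio test: identity, bookkeeping, null distribution", {
  d <- sim_ph_data(400, c(0.5, 0, 0), seed = 41)
  full <- fit_cox(d$outcomes, d$covariates)
  red <- fit_cox(d$outcomes, d$covariates[, "x1", drop = FALSE])
  same <- lrt_nested(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  lrt <- lrt_nested(full, red)
  expect_equal(lrt$df, 2)  # number of added terms
  expect_error(lrt_nested(red, full), "not nested")
  # under the null the statistic is approximately chi-square(df)
  set.seed(55)
  stats <- replicate(150, {
    d0 <- sim_ph_data(120, c(0.5, 0, 0))
    f <- fit_cox(d0$outcomes, d0$covariates)
    r <- fit_cox(d0$outcomes, d0$covariates[, "x1", drop = FALSE])
    lrt_nested(f, r)$statistic
  })
  qq_theory <- qchisq(c(0.25, 0.5, 0.75), df = 2)
  qq_emp <- quantile(stats, c(0.25, 0.5, 0.75))
  expect_equal(unname(qq_emp), qq_theory, tolerance = 0.35)
})
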