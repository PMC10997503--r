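#' Calibration slope of a prognostic index
#'
#' The estimated log-hazard ratio from a univariable Cox model with the
#' score as the only predictor, together with a Wald test of the null
#' hypothesis that the slope equals one. A slope below 1 indicates weaker
#' discrimination in the validation data than in the development data.
#'
#' @param scores numeric vector of prognostic index values.
#' @param outcomes data frame with `time` and `event` columns.
#' @param tie_method passed to [fit_cox()].
#' @return list with `slope`, `se`, `p_vs_one` and the univariable
#'   `cox_fit` in `$fit`.
#' @export
calibration_slope <- function(scores, outcomes,
                              tie_method = c("efron", "breslow")) {
  if (length(unique(scores)) < 2) {
    stop("scores are constant; calibration slope undefined", call. = FALSE)
  }
  fit <- fit_cox(outcomes, data.frame(score = scores),
                 tie_method = match.arg(tie_method))
  slope <- unname(fit$coefficients["score"])
  se <- sqrt(fit$covariance["score", "score"])
  z <- (slope - 1) / se
  list(slope = slope, se = se, p_vs_one = 2 * pnorm(-abs(z)), fit = fit)
}

#' Harrell's concordance index
#'
#' Proportion of usable patient pairs ordered concordantly by the score:
#' among pairs whose earlier observed time is an event, the pair is
#' concordant when the higher score goes with the shorter time; tied
#' scores receive 0.5 credit. Pairs tied on time where both are events
#' are usable with 0.5 credit (no correct ordering exists); time ties
#' between an event and a censoring treat the censored subject as
#' surviving past the tie.
#'
#' @param scores numeric vector (higher = higher predicted hazard).
#' @param outcomes data frame with `time` and `event` columns.
#' @return concordance index in `[0, 1]`.
#' @examples
#' harrell_c(c(3, 2, 1),
#'           data.frame(time = c(1, 2, 3), event = c(1, 1, 1)))  # 1
#' @export
harrell_c <- function(scores, outcomes) {
  if (length(scores) != nrow(outcomes)) stop("length mismatch")
  if (length(scores) < 2) stop("need at least two subjects")
  if (anyNA(scores) || anyNA(outcomes$time) || anyNA(outcomes$event)) {
    stop("missing values in scores or outcomes")
  }
  res <- harrell_c_pairs(as.numeric(scores), as.numeric(outcomes$time),
                         as.integer(outcomes$event))
  if (res[["usable"]] == 0) {
    stop("no usable pairs; concordance undefined", call. = FALSE)
  }
  res[["credit"]] / res[["usable"]]
}

#' Wald test of coefficient equality against a reference set
#'
#' Quadratic form `(b - b0)' V^-1 (b - b0)` comparing a refit model's
#' coefficients to fixed reference values (e.g. a published equation),
#' against a chi-square with one degree of freedom per coefficient. The
#' refit covariance is used alone, the reference being treated as a set of
#' known constants; this is an approximation when the reference itself was
#' estimated.
#'
#' @param fit a [fit_cox()] result.
#' @param reference a [coefficient_set()] (or named vector) with the same
#'   covariate names as `fit`.
#' @return list with `statistic`, `df`, `p`.
#' @export
coefficient_equality_test <- function(fit, reference) {
  stopifnot(inherits(fit, "cox_fit"))
  b0 <- .coef_vector(reference)
  b <- fit$coefficients
  if (!setequal(names(b), names(b0))) {
    stop("covariate names differ between fit and reference", call. = FALSE)
  }
  b0 <- b0[names(b)]
  d <- b - b0
  Vi <- tryCatch(solve(fit$covariance),
                 error = function(e) stop("singular covariance", call. = FALSE))
  stat <- drop(t(d) %*% Vi %*% d)
  df <- length(b)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Bootstrap optimism correction of the concordance index
#'
#' Harrell's internal validation procedure: for each of `B` bootstrap
#' resamples, refit the model on the resample, compute its concordance on
#' the resample (bootstrap-apparent) and on the original data
#' (bootstrap-test). Optimism is the mean difference, and the corrected
#' index is the apparent index minus the optimism. The analogous shrinkage
#' estimate for the calibration slope (mean slope of the original data on
#' each bootstrap model's scores) is also returned.
#'
#' @param outcomes data frame with `time` and `event`.
#' @param covariates numeric data frame, one row per outcome.
#' @param B number of bootstrap resamples (the reference analysis used
#'   1000; smaller values are adequate for the stable fits typical here).
#' @param seed integer seed; results are reproducible given `seed`.
#' @param tie_method passed to [fit_cox()].
#' @return list with `apparent_c`, `optimism`, `corrected_c`,
#'   `slope_shrinkage`, `B_failed`.
#' @export
bootstrap_optimism <- function(outcomes, covariates, B = 200, seed = 1,
                               tie_method = c("efron", "breslow")) {
  tie_method <- match.arg(tie_method)
  stopifnot(B >= 1)
  covariates <- as.data.frame(covariates)
  n <- nrow(outcomes)
  fit0 <- fit_cox(outcomes, covariates, tie_method)
  lp0 <- linear_predictor(fit0, covariates)
  apparent <- harrell_c(lp0, outcomes)
  set.seed(seed)
  opt <- numeric(0)
  slopes <- numeric(0)
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    # resample refits may be unstable in small samples; they are used
    # as-is (that instability is exactly what optimism measures), so
    # convergence warnings are silenced and only hard failures counted
    fb <- tryCatch(
      suppressWarnings(fit_cox(outcomes[idx, , drop = FALSE],
                               covariates[idx, , drop = FALSE], tie_method)),
      error = function(e) NULL
    )
    if (is.null(fb)) { failed <- failed + 1L; next }
    lp_boot <- linear_predictor(fb, covariates[idx, , drop = FALSE])
    lp_orig <- linear_predictor(fb, covariates)
    c_boot <- harrell_c(lp_boot, outcomes[idx, , drop = FALSE])
    c_orig <- harrell_c(lp_orig, outcomes)
    opt <- c(opt, c_boot - c_orig)
    sl <- tryCatch(suppressWarnings(calibration_slope(lp_orig, outcomes)$slope),
                   error = function(e) NA_real_)
    slopes <- c(slopes, sl)
  }
  if (failed > 0.1 * B) {
    stop(failed, " of ", B, " bootstrap refits failed", call. = FALSE)
  }
  optimism <- mean(opt)
  list(apparent_c = apparent, optimism = optimism,
       corrected_c = apparent - optimism,
       slope_shrinkage = mean(slopes, na.rm = TRUE), B_failed = failed)
}

#' Binned calibration curve at a horizon
#'
#' Groups patients into score bins (deciles by default), and compares the
#' mean model-predicted event-free probability at the horizon
#' (`s0(h)^exp(score)` from the baseline survival) with the within-bin
#' Kaplan-Meier estimate at the horizon.
#'
#' @param scores prognostic index values (uncentered linear predictors on
#'   the same reference as `baseline`).
#' @param outcomes data frame with `time` and `event`.
#' @param baseline a [baseline_survival()] object.
#' @param horizon evaluation time in years; must not exceed the last
#'   observed time.
#' @param bins number of equal-frequency score bins, at least 2 (use
#'   [km_estimate()] directly for the marginal comparison).
#' @return data frame with one row per bin: `bin`, `n`, `mean_predicted`,
#'   `observed_km`, `km_se`.
#' @export
calibration_curve <- function(scores, outcomes, baseline, horizon,
                              bins = 10) {
  stopifnot(bins >= 1)
  if (horizon > max(outcomes$time)) {
    stop("horizon exceeds the last observed time", call. = FALSE)
  }
  s0h <- survival_at(baseline, horizon)
  pred <- s0h^exp(scores)
  if (bins == 1) {
    grp <- factor(rep(1L, length(scores)))
  } else {
    br <- unique(quantile(scores, probs = seq(0, 1, length.out = bins + 1)))
    grp <- cut(scores, breaks = br, include.lowest = TRUE)
  }
  res <- lapply(levels(grp), function(g) {
    sel <- grp == g
    km <- km_estimate(outcomes[sel, , drop = FALSE])
    data.frame(bin = g, n = sum(sel),
               mean_predicted = mean(pred[sel]),
               observed_km = survival_at(km, horizon),
               km_se = km_se_at(km, horizon))
  })
  do.call(rbind, res)
}

#' External validation battery for a published prognostic index
#'
#' Runs the multi-step validation of a coefficient set on new data:
#' (1) overall calibration slope with a test of slope = 1; (2) Harrell's
#' concordance index of the score; (3) refit of the same covariates on the
#' validation data with a Wald test of coefficient equality against the
#' published values; (4) Kaplan-Meier curves within score-defined groups
#' with a log-rank comparison.
#'
#' @param coeffs a [coefficient_set()].
#' @param cohort patient table (see [cohort-schema]).
#' @param endpoint endpoint passed to [derive_endpoint()].
#' @param group_breaks quantile probabilities used to form score groups for
#'   step (4); default quartiles.
#' @return object of class `pi_validation`: `calibration` (slope, se,
#'   p_vs_one), `c_index`, `refit` (`cox_fit`), `coefficient_test`,
#'   `km_groups` (list of [km_estimate()] curves), `logrank`, `n_used`,
#'   `n_dropped`.
#' @export
validate_pi <- function(coeffs, cohort, endpoint = "rfs",
                        group_breaks = c(0.25, 0.5, 0.75)) {
  outcomes <- derive_endpoint(cohort, endpoint)
  kept <- setdiff(seq_len(nrow(cohort)), attr(outcomes, "excluded_rows"))
  sub <- cohort[kept, , drop = FALSE]
  covs <- encode_covariates(sub, covariates = names(.coef_vector(coeffs)),
                            na_action = "omit")
  rows <- setdiff(seq_len(nrow(sub)), attr(covs, "dropped_rows"))
  outcomes <- outcomes[rows, , drop = FALSE]
  scores <- score_pi(coeffs, covs)
  cal <- calibration_slope(scores, outcomes)
  cidx <- harrell_c(scores, outcomes)
  refit <- fit_cox(outcomes, covs)
  ct <- coefficient_equality_test(refit, coeffs)
  br <- unique(c(-Inf, quantile(scores, group_breaks), Inf))
  grp <- cut(scores, breaks = br)
  km <- lapply(split(outcomes, grp), km_estimate)
  lr <- logrank(split(outcomes, grp))
  structure(list(calibration = cal[c("slope", "se", "p_vs_one")],
                 c_index = cidx, refit = refit, coefficient_test = ct,
                 scores = scores, groups = grp, outcomes = outcomes,
                 km_groups = km, logrank = lr,
                 n_used = nrow(outcomes), n_dropped = attr(covs, "n_dropped"),
                 endpoint = attr(outcomes, "endpoint")),
            class = "pi_validation")
}

#' @export
print.pi_validation <- function(x, ...) {
  cat(sprintf("External validation (%s endpoint), n = %d (%d dropped)\n",
              x$endpoint, x$n_used, x$n_dropped))
  cat(sprintf("  calibration slope: %.3f (SE %.3f), p(slope = 1) = %.3g\n",
              x$calibration$slope, x$calibration$se, x$calibration$p_vs_one))
  cat(sprintf("  C-index: %.3f\n", x$c_index))
  cat(sprintf("  coefficient equality: chi2(%d) = %.2f, p = %.3g\n",
              x$coefficient_test$df, x$coefficient_test$statistic,
              x$coefficient_test$p))
  cat(sprintf("  log-rank across score groups: chi2(%d) = %.2f, p = %.3g\n",
              x$logrank$df, x$logrank$statistic, x$logrank$p))
  invisible(x)
}
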