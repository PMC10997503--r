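#' Fit a proportional-hazards model
#'
#' Maximum partial-likelihood Cox regression of a survival outcome on a
#' covariate matrix. Estimation is delegated to [survival::coxph()]
#' (Newton-Raphson, relative log-likelihood tolerance 1e-9, at most 100
#' iterations); this wrapper enforces the package's contracts (at least one
#' event, no constant or collinear column) and returns a compact fit
#' object whose linear predictor is uncentered, so scores reproduce the
#' printed index equations verbatim.
#'
#' @param outcomes data frame with numeric `time` and 0/1 `event` columns
#'   (see [derive_endpoint()]).
#' @param covariates numeric data frame or matrix, one row per outcome.
#' @param tie_method `"efron"` (default) or `"breslow"`. The two agree
#'   exactly when no event times are tied.
#' @return object of class `cox_fit`: `coefficients` (named log hazard
#'   ratios), `covariance` (inverse observed information), `loglik`,
#'   `loglik_null`, `n`, `n_events`, `tie_method`, and the underlying
#'   `coxph` fit in `$fit`.
#' @export
fit_cox <- function(outcomes, covariates, tie_method = c("efron", "breslow")) {
  tie_method <- match.arg(tie_method)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(outcomes)) {
    stop("outcomes and covariates must have the same number of rows")
  }
  if (anyNA(outcomes$time) || anyNA(outcomes$event) || anyNA(covariates)) {
    stop("missing values in outcomes or covariates; apply the complete-case ",
         "policy first (encode_covariates(..., na_action = \"omit\"))")
  }
  if (sum(outcomes$event) < 1) {
    stop("cannot fit: no events in the outcome data", call. = FALSE)
  }
  sds <- vapply(covariates, function(v) stats::sd(v), numeric(1))
  if (any(sds == 0)) {
    stop("constant covariate column: ",
         names(covariates)[which(sds == 0)[1L]], call. = FALSE)
  }
  dat <- cbind(.time = outcomes$time, .event = outcomes$event, covariates)
  fit <- survival::coxph(
    survival::Surv(.time, .event) ~ ., data = dat, ties = tie_method,
    x = TRUE, control = survival::coxph.control(eps = 1e-9, iter.max = 100)
  )
  if (anyNA(stats::coef(fit))) {
    stop("singular fit; collinear column: ",
         names(stats::coef(fit))[which(is.na(stats::coef(fit)))[1L]],
         call. = FALSE)
  }
  beta <- stats::coef(fit)
  names(beta) <- names(covariates)
  V <- stats::vcov(fit)
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(coefficients = beta, covariance = V,
                 loglik = fit$loglik[2L], loglik_null = fit$loglik[1L],
                 n = fit$n, n_events = fit$nevent,
                 tie_method = tie_method, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit: n = %d, events = %d, ties = %s, loglik = %.3f\n",
              x$n, x$n_events, x$tie_method, x$loglik))
  print(hazard_ratios(x), digits = 4)
  invisible(x)
}

#' Uncentered linear predictor
#'
#' Dot product of a coefficient vector with covariate values, with no
#' centering. Identical to [score_pi()]; provided under the modelling
#' vocabulary for use with [fit_cox()] results.
#'
#' @inheritParams score_pi
#' @return numeric vector of linear predictor values.
#' @export
linear_predictor <- function(coeffs, covariates) {
  score_pi(coeffs, covariates)
}

#' Baseline survival function of a Cox fit
#'
#' Breslow-type cumulative baseline hazard, exponentiated to a survival
#' step function referenced to all covariates equal to zero (consistent
#' with the uncentered linear predictor): `S(t | x) = s0(t)^exp(lp)`.
#'
#' @param fit a [fit_cox()] result.
#' @return object of class `baseline_survival` with sorted `times` and
#'   non-increasing `s0` in (0, 1]; evaluate with [survival_at()].
#' @export
baseline_survival <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  bh <- survival::basehaz(fit$fit, centered = FALSE)
  structure(list(times = bh$time, s0 = exp(-bh$hazard)),
            class = "baseline_survival")
}

#' Evaluate a step survival function
#'
#' Right-continuous lookup: the value at the largest tabulated time not
#' exceeding `t`, and 1 before the first event time.
#'
#' @param curve a `baseline_survival` or [km_estimate()] object.
#' @param t numeric vector of times.
#' @return numeric vector of survival probabilities.
#' @export
survival_at <- function(curve, t) {
  times <- curve$times
  surv <- if (!is.null(curve$s0)) curve$s0 else curve$survival
  idx <- findInterval(t, times)
  ifelse(idx == 0, 1, surv[pmax(idx, 1L)])
}

#' Proportional-hazards diagnostics
#'
#' Scaled Schoenfeld residuals at event times with a per-covariate
#' score test of zero slope against time (via [survival::cox.zph()] with
#' the identity time transform), and per-subject delta-beta (dfbeta)
#' approximations of coefficient influence.
#'
#' @param fit a [fit_cox()] result.
#' @return list with components `schoenfeld` (list: `time`, `scaled`
#'   matrix of scaled residuals, `raw` matrix of raw residuals, `table`
#'   of per-covariate chi-square slope tests with p-values) and `dfbeta`
#'   (n x p matrix: approximate change in each coefficient if the subject
#'   were removed).
#' @export
ph_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$n_events < 3) {
    stop("diagnostics unavailable: fewer than 3 events", call. = FALSE)
  }
  zph <- survival::cox.zph(fit$fit, transform = "identity")
  raw <- stats::residuals(fit$fit, type = "schoenfeld")
  raw <- as.matrix(raw)
  colnames(raw) <- names(fit$coefficients)
  scaled <- as.matrix(zph$y)
  colnames(scaled) <- names(fit$coefficients)
  dfb <- stats::residuals(fit$fit, type = "dfbeta")
  dfb <- as.matrix(dfb)
  colnames(dfb) <- names(fit$coefficients)
  list(
    schoenfeld = list(time = zph$time, scaled = scaled, raw = raw,
                      table = zph$table),
    dfbeta = dfb
  )
}

#' Likelihood-ratio test of nested Cox models
#'
#' `2 * (loglik_full - loglik_reduced)` against a chi-square reference
#' with degrees of freedom equal to the number of added coefficients.
#' Both fits must be on the same data, with the reduced model's
#' covariates a subset of the full model's.
#'
#' @param fit_full,fit_reduced [fit_cox()] results.
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt_nested <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "cox_fit"), inherits(fit_reduced, "cox_fit"))
  if (!all(names(fit_reduced$coefficients) %in% names(fit_full$coefficients))) {
    stop("models are not nested: reduced covariates ",
         "are not a subset of the full model's", call. = FALSE)
  }
  if (fit_full$n != fit_reduced$n || fit_full$n_events != fit_reduced$n_events) {
    stop("nested test requires both models fit to the same data", call. = FALSE)
  }
  df <- length(fit_full$coefficients) - length(fit_reduced$coefficients)
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  list(statistic = stat, df = df,
       p = if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE))
}
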