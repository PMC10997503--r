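#' Configuration for the synthetic cohort generator
#'
#' Default values emulate the covariate marginals of the combined COG
#' B-ALL trial population: favorable genetics in 45.4\% and unfavorable in
#' 5.9\% of patients (mutually exclusive), CNS1/2/3 in roughly
#' 87.9/10.4/1.3\%, log-normal WBC with median 8.7 x 10^9/L, age with
#' median 4.83 years on the range 1.0-30.8, and day-8 / day-29 MRD drawn
#' from the observed four-category frequencies (<0.01\%, 0.01-<0.1\%,
#' 0.1-<1\%, >=1\%) with log-uniform values within category and a
#' Gaussian-copula rank correlation between the two time points. Event
#' times follow a proportional-hazards model with a Weibull baseline whose
#' scale is calibrated numerically so that the marginal 5-year
#' relapse-free survival hits `target_rfs5`; censoring is uniform on
#' `censor_window`. Event-type bookkeeping (relapse vs remission death,
#' induction deaths/failures, deaths after relapse, missing MRD) mirrors
#' the observed frequencies and affects only endpoint derivation, not the
#' hazards.
#'
#' @param n cohort size.
#' @param seed integer seed; a fixed seed makes [simulate_cohort()] fully
#'   reproducible.
#' @param p_frg,p_urg marginal probabilities of the favorable /
#'   unfavorable genetics flags.
#' @param p_cns length-3 probability vector over CNS1/2/3.
#' @param wbc_log_median,wbc_log_sd location (median of log WBC) and SD of
#'   the log-normal WBC distribution.
#' @param age_median,age_sd,age_range log-normal age parameters (median in
#'   years, SD on the log scale) truncated to `age_range`.
#' @param mrd_category_probs_d29,mrd_category_probs_d8 length-4
#'   probability vectors over the MRD categories above.
#' @param mrd_copula_rho Gaussian-copula correlation between day-8 and
#'   day-29 MRD.
#' @param true_coeffs [coefficient_set()] generating the hazards; default
#'   the shipped COG index.
#' @param baseline_shape Weibull shape of the baseline hazard (< 1 gives
#'   the early-relapse-heavy shape typical of this disease).
#' @param baseline_scale Weibull scale; `NULL` (default) calibrates it to
#'   `target_rfs5`.
#' @param target_rfs5 marginal 5-year event-free probability used for
#'   calibration.
#' @param censor_window `c(min, max)` years of uniform censoring.
#' @param p_relapse_given_event fraction of post-induction events that are
#'   relapses (the rest are remission deaths).
#' @param p_induction_death,p_induction_failure probabilities of failing
#'   induction (such records never enter the relapse-free cohort).
#' @param p_death_after_relapse probability a relapse is followed by death;
#'   `post_relapse_death_mean` is the mean additional time in years.
#' @param post_relapse_death_mean see above.
#' @param p_missing_d8,p_missing_d29 missingness rates applied to the MRD
#'   columns after event generation.
#' @param p_training probability of the `"training"` cohort label.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n = 1000, seed = 1,
                       p_frg = 0.454, p_urg = 0.059,
                       p_cns = c(0.879, 0.104, 0.013),
                       wbc_log_median = log(8.7), wbc_log_sd = 1.4,
                       age_median = 4.83, age_sd = 0.62,
                       age_range = c(1.0, 30.8),
                       mrd_category_probs_d29 = c(0.782, 0.105, 0.071, 0.042),
                       mrd_category_probs_d8 = c(0.219, 0.262, 0.294, 0.225),
                       mrd_copula_rho = 0.5,
                       true_coeffs = pi_coefficients("published_cog"),
                       baseline_shape = 0.9, baseline_scale = NULL,
                       target_rfs5 = 0.90,
                       censor_window = c(4, 12),
                       p_relapse_given_event = 0.84,
                       p_induction_death = 0.008,
                       p_induction_failure = 0.005,
                       p_death_after_relapse = 0.3,
                       post_relapse_death_mean = 1,
                       p_missing_d8 = 0.236, p_missing_d29 = 0.034,
                       p_training = 0.623) {
  p_cns <- p_cns / sum(p_cns)
  mrd_category_probs_d29 <- mrd_category_probs_d29 / sum(mrd_category_probs_d29)
  mrd_category_probs_d8 <- mrd_category_probs_d8 / sum(mrd_category_probs_d8)
  cfg <- as.list(environment())
  for (p in c("p_frg", "p_urg", "p_relapse_given_event", "p_induction_death",
              "p_induction_failure", "p_death_after_relapse", "p_missing_d8",
              "p_missing_d29", "p_training")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop("invalid probability: ", p)
  }
  if (p_frg + p_urg > 1) stop("p_frg + p_urg must not exceed 1")
  if (length(p_cns) != 3 || any(p_cns < 0)) stop("invalid p_cns")
  if (length(mrd_category_probs_d29) != 4 || length(mrd_category_probs_d8) != 4)
    stop("MRD category probabilities must have length 4")
  if (baseline_shape <= 0) stop("baseline_shape must be positive")
  if (!is.null(baseline_scale) && baseline_scale <= 0)
    stop("baseline_scale must be positive")
  if (censor_window[1] < 0 || diff(censor_window) < 0)
    stop("invalid censor_window")
  structure(cfg, class = "sim_config")
}

#' Inverse-transform Weibull event times under proportional hazards
#'
#' Draws an event time from `S(t | x) = S0(t)^exp(lp)` with Weibull
#' baseline `S0(t) = exp(-(t / scale)^shape)`:
#' `t = scale * (-log(u) * exp(-lp))^(1/shape)`. For a fixed `u`, a higher
#' linear predictor gives a strictly smaller time.
#'
#' @param lp linear predictor values.
#' @param shape,scale Weibull baseline parameters (`shape = 1` is
#'   exponential).
#' @param u uniform(0, 1) draws (same length as `lp`).
#' @return event times in years.
#' @export
simulate_event_times <- function(lp, shape, scale, u) {
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly in (0, 1)")
  scale * (-log(u) * exp(-lp))^(1 / shape)
}

#' Calibrate the Weibull baseline scale to a marginal survival target
#'
#' Solves `mean(exp(-(horizon / scale)^shape * exp(lp))) = target` for the
#' scale, so that a cohort with the given linear predictors has the
#' requested marginal event-free probability at the horizon.
#'
#' @param lp linear predictor values of the cohort.
#' @param shape Weibull shape.
#' @param target marginal survival probability at `horizon`.
#' @param horizon years; default 5.
#' @return the calibrated scale (years).
#' @export
calibrate_baseline_scale <- function(lp, shape, target = 0.90, horizon = 5) {
  stopifnot(target > 0, target < 1)
  f <- function(log_scale) {
    mean(exp(-(horizon / exp(log_scale))^shape * exp(lp))) - target
  }
  exp(uniroot(f, c(log(1e-3), log(1e6)), tol = 1e-10)$root)
}

# within-category log-uniform MRD value; u is the copula uniform
.mrd_from_u <- function(u, probs) {
  bounds <- c(1e-6, 1e-4, 1e-3, 1e-2, 1)
  cum <- c(0, cumsum(probs))
  cat <- findInterval(u, cum, rightmost.closed = TRUE)
  cat <- pmin(pmax(cat, 1L), 4L)
  pos <- (u - cum[cat]) / probs[cat]
  exp(log(bounds[cat]) + pos * (log(bounds[cat + 1L]) - log(bounds[cat])))
}

#' Generate a synthetic B-ALL cohort
#'
#' Draws covariates, latent event times and observed event bookkeeping
#' according to a [sim_config()]; see that help page for the generative
#' model. NCI risk is derived from the standard age/WBC criteria (high
#' risk when age >= 10 years or WBC >= 50 x 10^9/L). The returned table
#' follows the [cohort-schema] and adds two generator-only columns with
#' the latent truths: `true_lp` (the generating linear predictor) and
#' `latent_event_time` (the uncensored event time); the calibrated
#' baseline parameters are stored in the `"baseline"` attribute.
#'
#' @param config a [sim_config()].
#' @return cohort data frame (validates under [validate_cohort()]).
#' @examples
#' coh <- simulate_cohort(sim_config(n = 200, seed = 42))
#' mean(coh$frg)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  gen <- sample(c("frg", "urg", "none"), n, replace = TRUE,
                prob = c(config$p_frg, config$p_urg,
                         1 - config$p_frg - config$p_urg))
  cns <- sample(c("CNS1", "CNS2", "CNS3"), n, replace = TRUE,
                prob = config$p_cns)
  wbc <- exp(rnorm(n, config$wbc_log_median, config$wbc_log_sd))
  # truncated log-normal age via inverse CDF
  mu_a <- log(config$age_median)
  plo <- stats::plnorm(config$age_range[1], mu_a, config$age_sd)
  phi <- stats::plnorm(config$age_range[2], mu_a, config$age_sd)
  age <- stats::qlnorm(runif(n, plo, phi), mu_a, config$age_sd)
  # Gaussian copula between D8 and D29 MRD
  z1 <- rnorm(n)
  z2 <- config$mrd_copula_rho * z1 +
    sqrt(1 - config$mrd_copula_rho^2) * rnorm(n)
  d8 <- .mrd_from_u(pnorm(z1), config$mrd_category_probs_d8)
  d29 <- .mrd_from_u(pnorm(z2), config$mrd_category_probs_d29)
  nci <- ifelse(age >= 10 | wbc >= 50, "HR", "SR")

  covs <- data.frame(
    tau_d29 = tau_mrd(d29), tau_d8 = tau_mrd(d8),
    frg = as.numeric(gen == "frg"), urg = as.numeric(gen == "urg"),
    wbc_log = wbc_log(wbc),
    cns2 = as.numeric(cns == "CNS2"), cns3 = as.numeric(cns == "CNS3"),
    age = age
  )
  beta <- .coef_vector(config$true_coeffs)
  lp <- score_pi(config$true_coeffs, covs[, names(beta), drop = FALSE])
  scale <- config$baseline_scale
  if (is.null(scale)) {
    scale <- calibrate_baseline_scale(lp, config$baseline_shape,
                                      config$target_rfs5)
  }
  tev <- simulate_event_times(lp, config$baseline_shape, scale, runif(n))
  cens <- runif(n, config$censor_window[1], config$censor_window[2])

  u_ind <- runif(n)
  ind_death <- u_ind < config$p_induction_death
  ind_fail <- !ind_death &
    u_ind < config$p_induction_death + config$p_induction_failure
  had_event <- !ind_death & !ind_fail & tev <= cens
  relapse <- had_event & runif(n) < config$p_relapse_given_event

  event_type <- rep("none", n)
  event_type[ind_death] <- "induction_death"
  event_type[ind_fail] <- "induction_failure"
  event_type[had_event & relapse] <- "relapse"
  event_type[had_event & !relapse] <- "remission_death"
  time <- ifelse(had_event, tev, cens)
  time[ind_death | ind_fail] <- 0

  # overall-survival bookkeeping
  death_flag <- integer(n)
  death_time <- cens
  death_flag[event_type %in% c("remission_death", "induction_death")] <- 1L
  death_time[event_type == "remission_death"] <-
    time[event_type == "remission_death"]
  death_time[event_type == "induction_death"] <- 0
  rel <- which(event_type == "relapse")
  dies <- rel[runif(length(rel)) < config$p_death_after_relapse]
  death_flag[dies] <- 1L
  death_time[dies] <- time[dies] +
    stats::rexp(length(dies), 1 / config$post_relapse_death_mean)

  d8_obs <- ifelse(runif(n) < config$p_missing_d8, NA, d8)
  d29_obs <- ifelse(runif(n) < config$p_missing_d29, NA, d29)

  cohort <- data.frame(
    id = sprintf("P%06d", seq_len(n)),
    age_years = age, wbc = wbc,
    d8_mrd = d8_obs, d29_mrd = d29_obs,
    frg = gen == "frg", urg = gen == "urg",
    cns = cns, nci_risk = nci,
    event_type = event_type, time_from_eoi_years = time,
    death_time = death_time, death_flag = death_flag,
    cohort_label = ifelse(runif(n) < config$p_training,
                          "training", "testing"),
    true_lp = lp, latent_event_time = tev,
    stringsAsFactors = FALSE
  )
  validate_cohort(cohort)
  attr(cohort, "baseline") <- c(shape = config$baseline_shape, scale = scale)
  cohort
}
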