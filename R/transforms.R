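#' Floored negative-log transformation of minimal residual disease
#'
#' Maps an MRD value on the fraction scale (0.01\% == 1e-4) to the
#' transformed scale used by the prognostic index: `-log(mrd)` for
#' quantifiable disease, with every value below the quantification
#' threshold (including 0 and undetectable) assigned the fixed floor
#' `-log(floor_fraction)`. With the defaults the floor is
#' `-log(1e-6) = 13.8155` (13.82 at two decimals), so higher transformed
#' values mean less residual disease.
#'
#' @param mrd numeric vector of MRD fractions in `[0, 1]`; `NA` propagates.
#' @param floor_fraction fraction substituted for values below
#'   `cap_threshold`; default `1e-6`.
#' @param cap_threshold quantification threshold below which the floor
#'   applies; default `1e-5`.
#' @param base logarithm base; default natural log.
#' @return numeric vector on the transformed ("tau") scale.
#' @examples
#' tau_mrd(1e-4)   # 9.2103
#' tau_mrd(0)      # 13.8155, the floor
#' @export
tau_mrd <- function(mrd, floor_fraction = 1e-6, cap_threshold = 1e-5,
                    base = exp(1)) {
  if (!is.numeric(mrd)) stop("`mrd` must be numeric")
  bad <- !is.na(mrd) & (mrd < 0 | mrd > 1)
  if (any(bad)) {
    stop("MRD values must lie in [0, 1] (fraction scale); offending value: ",
         mrd[bad][1L])
  }
  out <- -log(mrd, base = base)
  floorv <- -log(floor_fraction, base = base)
  out[!is.na(mrd) & mrd < cap_threshold] <- floorv
  out
}

#' Log-transformed white blood cell count
#'
#' Natural logarithm (by default) of the presenting WBC in units of
#' 10^9 cells/L.
#'
#' @param wbc positive numeric vector; `NA` propagates.
#' @param base logarithm base; default natural log.
#' @return numeric vector of log WBC.
#' @examples
#' wbc_log(8.7)  # 2.1633
#' @export
wbc_log <- function(wbc, base = exp(1)) {
  if (!is.numeric(wbc)) stop("`wbc` must be numeric")
  bad <- !is.na(wbc) & wbc <= 0
  if (any(bad)) stop("WBC must be positive; offending value: ", wbc[bad][1L])
  log(wbc, base = base)
}

#' Build the model covariate matrix from a patient table
#'
#' Applies [tau_mrd()] to the day-29 and day-8 MRD columns, [wbc_log()] to
#' WBC, and dummy-codes CNS status against the CNS1 reference, yielding the
#' eight covariates of the full relapse model: `tau_d29`, `tau_d8`, `frg`,
#' `urg`, `wbc_log`, `cns2`, `cns3`, `age`.
#'
#' @param cohort patient data frame as returned by [read_cohort()] or
#'   [simulate_cohort()].
#' @param covariates character vector of required covariate names (a subset
#'   of the eight); defaults to all eight.
#' @param na_action `"error"` (default) raises a missing-covariate error
#'   naming the first offending field and row; `"omit"` drops incomplete
#'   records (complete-case policy) and records the count in the
#'   `"n_dropped"` attribute.
#' @return data frame of covariate columns, one row per retained record,
#'   with attributes `"n_dropped"` and `"dropped_rows"` when `na_action =
#'   "omit"`.
#' @export
encode_covariates <- function(cohort,
                              covariates = c("tau_d29", "tau_d8", "frg",
                                             "urg", "wbc_log", "cns2",
                                             "cns3", "age"),
                              na_action = c("error", "omit")) {
  na_action <- match.arg(na_action)
  covariates <- match.arg(covariates, several.ok = TRUE)
  n <- nrow(cohort)
  full <- data.frame(
    tau_d29 = tau_mrd(cohort$d29_mrd),
    tau_d8  = tau_mrd(cohort$d8_mrd),
    frg     = as.numeric(cohort$frg),
    urg     = as.numeric(cohort$urg),
    wbc_log = wbc_log(cohort$wbc),
    cns2    = as.numeric(cohort$cns == "CNS2"),
    cns3    = as.numeric(cohort$cns == "CNS3"),
    age     = cohort$age_years
  )[, covariates, drop = FALSE]
  # source field names for error messages
  src <- c(tau_d29 = "d29_mrd", tau_d8 = "d8_mrd", frg = "frg", urg = "urg",
           wbc_log = "wbc", cns2 = "cns", cns3 = "cns", age = "age_years")
  keep <- complete.cases(full)
  if (na_action == "error" && !all(keep)) {
    row <- which(!keep)[1L]
    col <- names(full)[which(is.na(full[row, ]))[1L]]
    stop("missing covariate '", src[[col]], "' (needed for '", col,
         "') in record ", row, call. = FALSE)
  }
  out <- full[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "dropped_rows") <- which(!keep)
  out
}
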