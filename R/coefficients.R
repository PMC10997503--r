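#' Create a named prognostic coefficient set
#'
#' A `coefficient_set` carries a named vector of log-hazard-ratio
#' coefficients, a provenance tag, and optionally a covariance matrix
#' (for fitted sets) and score cutpoints.
#'
#' @param name model name, e.g. `"PI_COG"`.
#' @param coefficients named numeric vector; names are covariate names,
#'   unique and finite.
#' @param provenance one of `"published_ukall"`, `"derived_ukall"`,
#'   `"published_cog"`, `"fitted"`.
#' @param covariance optional covariance matrix matching the coefficients.
#' @param cutpoints optional increasing numeric vector of score thresholds.
#' @return object of class `coefficient_set`.
#' @export
coefficient_set <- function(name, coefficients,
                            provenance = c("fitted", "published_ukall",
                                           "derived_ukall", "published_cog"),
                            covariance = NULL, cutpoints = NULL) {
  provenance <- match.arg(provenance)
  if (is.null(names(coefficients)) || anyDuplicated(names(coefficients))) {
    stop("coefficients must have unique names")
  }
  if (!all(is.finite(coefficients))) stop("coefficients must be finite")
  if (!is.null(covariance)) {
    covariance <- as.matrix(covariance)
    stopifnot(nrow(covariance) == length(coefficients),
              ncol(covariance) == length(coefficients))
    dimnames(covariance) <- list(names(coefficients), names(coefficients))
  }
  if (!is.null(cutpoints) && is.unsorted(cutpoints, strictly = TRUE)) {
    stop("cutpoints must be strictly increasing")
  }
  structure(list(name = name, coefficients = coefficients,
                 provenance = provenance, covariance = covariance,
                 cutpoints = cutpoints),
            class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("Prognostic coefficient set:", x$name,
      sprintf("(%s)\n", x$provenance))
  print(round(x$coefficients, 4))
  if (!is.null(x$cutpoints)) {
    cat("cutpoints:", paste(round(x$cutpoints, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Shipped prognostic coefficient sets
#'
#' Loads one of the versioned coefficient configurations shipped with the
#' package:
#' \describe{
#'   \item{`"published_ukall"`}{the published UKALL relapse index: tau(D29
#'     MRD), good-risk and high-risk cytogenetics, log WBC. The UKALL
#'     cytogenetic groups (CYTO_GR / CYTO_HR) are mapped onto this cohort
#'     schema's `frg` / `urg` flags; the mapping lives in the config so
#'     alternative genetic definitions can be swapped in.}
#'   \item{`"derived_ukall"`}{the same four-covariate model refit on the
#'     COG analysis population.}
#'   \item{`"published_cog"`}{the eight-covariate COG index (adds tau(D8
#'     MRD), CNS2/CNS3 dummies and age), including its published
#'     risk-group cutpoints -1.377, -0.589, 0.093.}
#' }
#' Sets are stored as JSON config data rather than code constants so that
#' model updating is a config change.
#'
#' @param which set name.
#' @param file optional path to an alternative JSON config.
#' @return a [coefficient_set()].
#' @examples
#' pi_coefficients("published_cog")
#' @export
pi_coefficients <- function(which = c("published_cog", "published_ukall",
                                      "derived_ukall"),
                            file = NULL) {
  which <- match.arg(which)
  if (is.null(file)) {
    file <- system.file("extdata", "coefficient_sets.json", package = "mrdpi",
                        mustWork = TRUE)
  }
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  entry <- cfg[[which]]
  if (is.null(entry)) stop("no coefficient set '", which, "' in ", file)
  coefficient_set(
    name = entry$name,
    coefficients = setNames(entry$terms$coefficient, entry$terms$covariate),
    provenance = entry$provenance,
    cutpoints = entry$cutpoints
  )
}

.coef_vector <- function(coeffs) {
  if (inherits(coeffs, "coefficient_set")) coeffs$coefficients
  else if (inherits(coeffs, "cox_fit")) coeffs$coefficients
  else if (is.numeric(coeffs) && !is.null(names(coeffs))) coeffs
  else stop("expected a coefficient_set, cox_fit or named numeric vector")
}

#' Score patients with a prognostic index
#'
#' Computes the uncentered linear predictor `sum(beta * x)` for each record,
#' reproducing the printed index equations verbatim. Every covariate named
#' by the coefficient set must be present and non-missing.
#'
#' @param coeffs a [coefficient_set()], [fit_cox()] result, or named
#'   numeric vector of coefficients.
#' @param covariates data frame or matrix of covariates (one row per
#'   patient, see [encode_covariates()]), or a single named numeric vector.
#' @return numeric vector of prognostic index scores.
#' @examples
#' x <- c(tau_d29 = 9.2103, frg = 0, urg = 0, wbc_log = 2.9957)
#' score_pi(pi_coefficients("published_ukall"), x)  # -1.5944
#' @export
score_pi <- function(coeffs, covariates) {
  beta <- .coef_vector(coeffs)
  if (is.numeric(covariates) && is.null(dim(covariates))) {
    covariates <- as.data.frame(as.list(covariates))
  }
  miss <- setdiff(names(beta), colnames(covariates))
  if (length(miss)) {
    stop("missing covariate(s) required by the coefficient set: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(covariates[, names(beta), drop = FALSE])
  if (!is.numeric(x)) stop("covariates must be numeric")
  if (anyNA(x)) {
    row <- which(apply(is.na(x), 1L, any))[1L]
    col <- colnames(x)[which(is.na(x[row, ]))[1L]]
    stop("missing covariate '", col, "' in record ", row, call. = FALSE)
  }
  drop(x %*% beta)
}

#' Hazard ratios of a coefficient set
#'
#' `exp(coefficient)` per term, with Wald confidence limits
#' `exp(coefficient +/- z * SE)` when a covariance matrix is available.
#'
#' @param coeffs a [coefficient_set()] or [fit_cox()] result.
#' @param conf_level confidence level for the interval; default 0.95.
#' @return data frame with columns `covariate`, `coefficient`, `hr` and,
#'   when a covariance is available, `se`, `lower`, `upper`.
#' @export
hazard_ratios <- function(coeffs, conf_level = 0.95) {
  beta <- .coef_vector(coeffs)
  V <- if (inherits(coeffs, "coefficient_set")) coeffs$covariance
       else if (inherits(coeffs, "cox_fit")) coeffs$covariance
       else NULL
  out <- data.frame(covariate = names(beta), coefficient = unname(beta),
                    hr = unname(exp(beta)), stringsAsFactors = FALSE)
  if (!is.null(V)) {
    se <- sqrt(diag(V))
    z <- qnorm(1 - (1 - conf_level) / 2)
    out$se <- unname(se)
    out$lower <- unname(exp(beta - z * se))
    out$upper <- unname(exp(beta + z * se))
  }
  out
}
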