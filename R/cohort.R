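#' @name cohort-schema
#' @title Cohort table schema
#'
#' @description A cohort is a plain `data.frame` with one row per patient
#' and the columns below. Times are in years from end of induction (EOI);
#' MRD is stored internally on the fraction scale (0.01\% == 1e-4); missing
#' values are `NA` (empty cells on disk).
#'
#' \describe{
#'   \item{id}{character, unique}
#'   \item{age_years}{age at diagnosis, years, > 0}
#'   \item{wbc}{presenting WBC, 10^9/L, > 0}
#'   \item{d8_mrd, d29_mrd}{MRD fractions in `[0, 1]` or `NA`}
#'   \item{frg, urg}{favorable / unfavorable risk-genetics flags (logical;
#'     never both `TRUE`)}
#'   \item{cns}{`"CNS1"`, `"CNS2"` or `"CNS3"`}
#'   \item{nci_risk}{`"SR"`, `"HR"` or `NA`}
#'   \item{event_type}{one of `none`, `relapse`, `remission_death`, `smn`,
#'     `induction_death`, `induction_failure`}
#'   \item{time_from_eoi_years}{time to the event, or censoring time when
#'     `event_type == "none"`; >= 0}
#'   \item{death_time, death_flag}{optional; time to death or last contact
#'     and a 0/1 death indicator, used only for overall survival (deaths
#'     after relapse are not representable in `event_type` alone)}
#'   \item{cohort_label}{optional `"training"` / `"testing"` split marker}
#' }
NULL

.cns_levels <- c("CNS1", "CNS2", "CNS3")
.event_levels <- c("none", "relapse", "remission_death", "smn",
                   "induction_death", "induction_failure")
.required_cols <- c("id", "age_years", "wbc", "d8_mrd", "d29_mrd", "frg",
                    "urg", "cns", "event_type", "time_from_eoi_years")

#' Validate a cohort table against the schema
#'
#' Checks column presence, enum codes, value ranges and the
#' genetics-flag exclusivity invariant. Errors name the offending row and
#' column.
#'
#' @param cohort data frame (see [cohort-schema]).
#' @return the validated cohort, invisibly usable downstream.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(.required_cols, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  check_enum <- function(col, levels) {
    v <- cohort[[col]]
    bad <- which(!is.na(v) & !(v %in% levels))
    if (length(bad)) {
      stop("schema error: unknown code '", v[bad[1L]], "' in column '", col,
           "', row ", bad[1L], call. = FALSE)
    }
  }
  check_enum("cns", .cns_levels)
  check_enum("event_type", .event_levels)
  if ("nci_risk" %in% names(cohort)) check_enum("nci_risk", c("SR", "HR"))
  if (any(!is.na(cohort$cns) & is.na(match(cohort$cns, .cns_levels)))) {
    stop("schema error in column 'cns'")
  }
  tt <- cohort$time_from_eoi_years
  bad <- which(!is.na(tt) & tt < 0)
  if (length(bad)) {
    stop("validation error: negative time in column 'time_from_eoi_years', row ",
         bad[1L], call. = FALSE)
  }
  for (col in c("d8_mrd", "d29_mrd")) {
    v <- cohort[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad)) {
      stop("validation error: MRD outside [0, 1] in column '", col, "', row ",
           bad[1L], " (is the file on the percent scale?)", call. = FALSE)
    }
  }
  both <- which(!is.na(cohort$frg) & !is.na(cohort$urg) &
                  cohort$frg & cohort$urg)
  if (length(both)) {
    stop("validation error: frg and urg both TRUE in row ", both[1L],
         call. = FALSE)
  }
  bad <- which(!is.na(cohort$wbc) & cohort$wbc <= 0)
  if (length(bad)) {
    stop("validation error: non-positive WBC in row ", bad[1L], call. = FALSE)
  }
  bad <- which(!is.na(cohort$age_years) & cohort$age_years <= 0)
  if (length(bad)) {
    stop("validation error: non-positive age in row ", bad[1L], call. = FALSE)
  }
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads and validates a patient table in the [cohort-schema] layout.
#' Missing values are empty cells. MRD columns recorded on the percent
#' scale (0.01 meaning 0.01\%) are converted to fractions with
#' `mrd_unit = "percent"`.
#'
#' @param path CSV file path.
#' @param mrd_unit unit of the `d8_mrd`/`d29_mrd` columns on disk.
#' @return validated cohort data frame.
#' @export
read_cohort <- function(path, mrd_unit = c("fraction", "percent")) {
  mrd_unit <- match.arg(mrd_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"), colClasses = c(id = "character"))
  for (col in c("frg", "urg")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  if (mrd_unit == "percent") {
    for (col in c("d8_mrd", "d29_mrd")) df[[col]] <- df[[col]] / 100
  }
  if ("death_flag" %in% names(df)) df$death_flag <- as.integer(df$death_flag)
  validate_cohort(df)
  df
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()] (fraction scale, empty cells for `NA`).
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Derive survival outcomes from raw event records
#'
#' Turns a cohort's event bookkeeping into `(time, event)` pairs for one
#' endpoint, all measured from end of induction:
#' \describe{
#'   \item{RFS}{relapse or death in remission are events; a second
#'     malignant neoplasm (SMN) censors at its time; induction deaths and
#'     induction failures are excluded from the cohort (counted in the
#'     `"n_excluded"` attribute).}
#'   \item{DFS}{as RFS but SMN also counts as an event.}
#'   \item{OS}{death from any cause; uses the optional `death_time` /
#'     `death_flag` columns when present (deaths after relapse are not
#'     expressible through `event_type`), otherwise falls back to
#'     remission/induction deaths at the recorded event time.}
#' }
#'
#' @param cohort cohort data frame (see [cohort-schema]).
#' @param endpoint `"rfs"`, `"dfs"` or `"os"`.
#' @return data frame with columns `id`, `time`, `event` (0/1) and
#'   attributes `"endpoint"`, `"n_excluded"`, `"excluded_rows"` (rows of
#'   `cohort` not in the returned outcome set).
#' @export
derive_endpoint <- function(cohort, endpoint = c("rfs", "dfs", "os")) {
  endpoint <- match.arg(endpoint)
  validate_cohort(cohort)
  ev <- cohort$event_type
  if (endpoint %in% c("rfs", "dfs")) {
    excl <- which(ev %in% c("induction_death", "induction_failure"))
    keep <- setdiff(seq_len(nrow(cohort)), excl)
    sub <- cohort[keep, , drop = FALSE]
    event_set <- if (endpoint == "rfs") c("relapse", "remission_death")
                 else c("relapse", "remission_death", "smn")
    out <- data.frame(
      id = sub$id,
      time = sub$time_from_eoi_years,
      event = as.integer(sub$event_type %in% event_set),
      stringsAsFactors = FALSE
    )
  } else {
    excl <- integer(0)
    has_death <- all(c("death_time", "death_flag") %in% names(cohort)) &&
      any(!is.na(cohort$death_flag))
    if (has_death) {
      time <- ifelse(is.na(cohort$death_time),
                     cohort$time_from_eoi_years, cohort$death_time)
      event <- ifelse(is.na(cohort$death_flag),
                      as.integer(ev %in% c("remission_death", "induction_death")),
                      as.integer(cohort$death_flag))
    } else {
      time <- cohort$time_from_eoi_years
      event <- as.integer(ev %in% c("remission_death", "induction_death"))
    }
    out <- data.frame(id = cohort$id, time = time, event = event,
                      stringsAsFactors = FALSE)
  }
  if (any(is.na(out$time))) stop("missing follow-up time in cohort")
  structure(out, endpoint = toupper(endpoint),
            n_excluded = length(excl), excluded_rows = excl)
}
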