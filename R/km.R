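#' Kaplan-Meier product-limit estimate
#'
#' Product-limit survival estimate with Greenwood standard errors,
#' computed via [survival::survfit()]. Ties between events and censorings
#' at the same time treat events first (standard convention). Evaluate at
#' arbitrary times with [survival_at()] (right-continuous step lookup).
#'
#' @param outcomes data frame with non-negative `time` and 0/1 `event`.
#' @return object of class `km_curve`: sorted distinct event `times`,
#'   non-increasing `survival`, `greenwood_se`, and per-time `n_risk`,
#'   `n_event` counts.
#' @examples
#' km <- km_estimate(data.frame(time = c(1, 2, 3), event = c(1, 0, 1)))
#' survival_at(km, 1)  # 2/3
#' @export
km_estimate <- function(outcomes) {
  if (nrow(outcomes) < 1) stop("need at least one subject")
  if (any(outcomes$time < 0)) stop("negative times", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = outcomes, conf.type = "none")
  keep <- sf$n.event > 0
  structure(list(times = sf$time[keep], survival = sf$surv[keep],
                 greenwood_se = sf$std.err[keep] * sf$surv[keep],
                 n_risk = sf$n.risk[keep], n_event = sf$n.event[keep],
                 n = sf$n),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event times\n",
              x$n, length(x$times)))
  print(head(data.frame(time = x$times, n_risk = x$n_risk,
                        n_event = x$n_event, survival = x$survival,
                        se = x$greenwood_se), 10), digits = 4)
  invisible(x)
}

# Greenwood SE at time t (0 before the first event)
km_se_at <- function(km, t) {
  idx <- findInterval(t, km$times)
  ifelse(idx == 0, 0, km$greenwood_se[pmax(idx, 1L)])
}

#' Survival estimate at a horizon, with truncation flag
#'
#' Reads a [km_estimate()] curve at an exact horizon. If follow-up in the
#' group ends before the horizon, the last value carries forward and
#' `truncated` is `TRUE`.
#'
#' @param km a `km_curve`.
#' @param horizon time in years.
#' @param max_time latest observed time in the group (event or censoring);
#'   defaults to the last event time in the curve.
#' @return list with `estimate`, `se`, `truncated`.
#' @export
km_at_horizon <- function(km, horizon, max_time = NULL) {
  if (is.null(max_time)) {
    max_time <- if (length(km$times)) max(km$times) else 0
  }
  list(estimate = survival_at(km, horizon), se = km_se_at(km, horizon),
       truncated = horizon > max_time)
}

#' Log-rank test across outcome groups
#'
#' Standard log-rank chi-square comparison of two or more groups'
#' survival distributions, via [survival::survdiff()].
#'
#' @param outcome_groups list of two or more non-empty outcome data
#'   frames (each with `time` and `event`).
#' @return list with `statistic`, `df`, `p`.
#' @export
logrank <- function(outcome_groups) {
  if (!is.list(outcome_groups) || length(outcome_groups) < 2) {
    stop("need at least two groups", call. = FALSE)
  }
  sizes <- vapply(outcome_groups, nrow, integer(1))
  if (any(sizes == 0)) stop("empty group", call. = FALSE)
  dat <- do.call(rbind, lapply(seq_along(outcome_groups), function(i) {
    data.frame(time = outcome_groups[[i]]$time,
               event = outcome_groups[[i]]$event, group = i)
  }))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  df <- length(outcome_groups) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = pchisq(unname(sd$chisq), df, lower.tail = FALSE))
}
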