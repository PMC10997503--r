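#' Concordance probability estimate (Gonen-Heller)
#'
#' Model-based concordance of a set of linear predictors under the
#' proportional-hazards assumption: the average over unordered pairs with
#' distinct values of `1 / (1 + exp(-|eta_i - eta_j|))`. Pairs with tied
#' values are excluded from numerator and denominator by default
#' (`ties = "half"` instead keeps them with 0.5 credit). If all values are
#' tied the estimate is 0.5 by convention. The estimate never falls below
#' 0.5, since each included pair contributes at least 0.5.
#'
#' @param scores numeric vector of linear predictors, length >= 2.
#' @param ties `"exclude"` (default) or `"half"`.
#' @return concordance probability in `[0.5, 1)`.
#' @examples
#' cpe(c(0, 1))  # 1 / (1 + exp(-1)) = 0.7311
#' @export
cpe <- function(scores, ties = c("exclude", "half")) {
  ties <- match.arg(ties)
  if (length(scores) < 2) stop("need at least two scores", call. = FALSE)
  if (anyNA(scores)) stop("missing scores")
  res <- cpe_pairs(as.numeric(scores), ties == "half")
  if (res[["pairs"]] == 0) return(0.5)
  res[["total"]] / res[["pairs"]]
}

#' Create a cutpoint set
#'
#' Strictly increasing score thresholds partitioning a continuous
#' prognostic index into `length(cutpoints) + 1` ordered risk groups.
#'
#' @param cutpoints strictly increasing numeric vector.
#' @param labels ordered group names; defaults to Low, Standard,
#'   Intermediate, High for three cutpoints, otherwise `"G1"`, `"G2"`, ...
#' @return object of class `cutpoint_set`.
#' @export
cutpoint_set <- function(cutpoints, labels = NULL) {
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) < 1 || is.unsorted(cutpoints, strictly = TRUE)) {
    stop("cutpoints must be strictly increasing")
  }
  k <- length(cutpoints) + 1L
  if (is.null(labels)) {
    labels <- if (k == 4) c("Low", "Standard", "Intermediate", "High")
              else paste0("G", seq_len(k))
  }
  if (length(labels) != k) stop("need one label per group (cutpoints + 1)")
  structure(list(cutpoints = cutpoints, labels = labels),
            class = "cutpoint_set")
}

#' @export
print.cutpoint_set <- function(x, ...) {
  cat("Cutpoint set:", paste(round(x$cutpoints, 3), collapse = ", "),
      "->", paste(x$labels, collapse = " < "), "\n")
  invisible(x)
}

#' Published risk-group cutpoints for the COG prognostic index
#'
#' The shipped default cutpoints -1.377, -0.589, 0.093 partitioning the
#' COG index into Low, Standard, Intermediate and High relapse-risk
#' groups.
#'
#' @return a [cutpoint_set()].
#' @export
cog_cutpoints <- function() {
  cfg <- jsonlite::read_json(
    system.file("extdata", "coefficient_sets.json", package = "mrdpi",
                mustWork = TRUE), simplifyVector = TRUE)
  cutpoint_set(cfg$published_cog$cutpoints, cfg$published_cog$labels)
}

#' Assign ordered risk groups from a score
#'
#' Left-open / right-closed assignment: group `i` when
#' `c[i-1] < score <= c[i]` with `c0 = -Inf`, `ck = +Inf`, so a score
#' exactly on a cutpoint falls in the lower-risk group. Higher scores
#' never map to a lower-risk label.
#'
#' @param score numeric vector of prognostic index values.
#' @param cuts a [cutpoint_set()].
#' @return ordered factor of group labels.
#' @examples
#' assign_risk_group(c(-2.1, 0), cog_cutpoints())  # Low, Intermediate
#' @export
assign_risk_group <- function(score, cuts) {
  stopifnot(inherits(cuts, "cutpoint_set"))
  idx <- rowSums(outer(as.numeric(score), cuts$cutpoints, ">")) + 1L
  factor(cuts$labels[idx], levels = cuts$labels, ordered = TRUE)
}

#' CPE-optimal cutpoints for a prognostic index
#'
#' Exhaustive search for the `k - 1` score thresholds that maximize the
#' concordance probability estimate of an ordered-group refit. Candidate
#' thresholds are the empirical score quantiles on a grid; for each
#' feasible threshold tuple, patients are partitioned by
#' [assign_risk_group()], a Cox model is refit on the ordered-group
#' indicator covariates, and the CPE of its fitted linear predictors is
#' computed; the maximizing tuple is returned. Deterministic given its
#' inputs (ties broken toward the first tuple in enumeration order).
#'
#' @param scores numeric vector of prognostic index values.
#' @param outcomes data frame with `time` and `event` columns.
#' @param k_groups number of risk groups, at least 2; default 4.
#' @param grid_quantile_step quantile spacing of candidate thresholds
#'   (default 0.005; coarser values bound the size of the search).
#' @param min_group_frac minimum fraction of patients per group
#'   (default 0.05); infeasible settings (`k_groups * min_group_frac > 1`)
#'   raise an error.
#' @param labels passed to [cutpoint_set()].
#' @param ties CPE tie handling for the search objective. The default here
#'   is `"half"` (tied pairs kept with 0.5 credit), unlike [cpe()]: a
#'   grouped model ties every within-group pair, and excluding those pairs
#'   makes the objective blind to group sizes — it then degenerates toward
#'   sliver groups with noise-inflated coefficients. Half-credit inclusion
#'   keeps the estimate size-aware while preserving the 0.5 =
#'   no-discrimination convention.
#' @return list with `cutpoints` (a [cutpoint_set()]), `cpe` (achieved
#'   value), and `n_candidates` (tuples evaluated).
#' @export
find_cutpoints <- function(scores, outcomes, k_groups = 4,
                           grid_quantile_step = 0.005,
                           min_group_frac = 0.05, labels = NULL,
                           ties = c("half", "exclude")) {
  ties <- match.arg(ties)
  stopifnot(k_groups >= 2)
  if (k_groups * min_group_frac > 1) {
    stop("infeasible: k_groups * min_group_frac > 1", call. = FALSE)
  }
  if (length(scores) != nrow(outcomes)) stop("length mismatch")
  probs <- seq(grid_quantile_step, 1 - grid_quantile_step,
               by = grid_quantile_step)
  # candidate thresholds at quantile positions, placed midway between the
  # adjacent order statistics so that a candidate always exists in any
  # empty stretch of the score distribution
  s <- sort(scores)
  n <- length(s)
  k <- pmin(pmax(round(probs * n), 1L), n - 1L)
  cand <- data.frame(prob = k / n, value = (s[k] + s[k + 1L]) / 2)
  cand <- cand[!duplicated(cand$value), , drop = FALSE]
  if (nrow(cand) < k_groups - 1) {
    stop("not enough distinct score quantiles to form ", k_groups, " groups",
         call. = FALSE)
  }
  combs <- utils::combn(nrow(cand), k_groups - 1L)
  # prune by quantile spacing so every group can hold min_group_frac
  ok <- apply(combs, 2L, function(ix) {
    p <- c(0, cand$prob[ix], 1)
    all(diff(p) >= min_group_frac)
  })
  combs <- combs[, ok, drop = FALSE]
  if (ncol(combs) == 0) {
    stop("no feasible cutpoint tuple under min_group_frac = ", min_group_frac,
         call. = FALSE)
  }
  y <- survival::Surv(outcomes$time, outcomes$event)
  half <- ties == "half"
  best <- NULL
  best_cpe <- -Inf
  n_eval <- 0L
  for (j in seq_len(ncol(combs))) {
    cuts <- cand$value[combs[, j]]
    grp <- rowSums(outer(scores, cuts, ">")) + 1L
    cnt <- tabulate(grp, nbins = k_groups)
    if (any(cnt < max(1, floor(min_group_frac * length(scores))))) next
    g <- factor(grp, levels = seq_len(k_groups))
    # warnings (e.g. convergence notes on near-separated groups) are not
    # grounds to drop a candidate; only hard failures are
    fit <- tryCatch(
      suppressWarnings(survival::coxph(y ~ g, ties = "efron")),
      error = function(e) NULL
    )
    if (is.null(fit) || anyNA(stats::coef(fit))) next
    etas <- c(0, stats::coef(fit))
    res <- cpe_pairs_grouped(etas, as.numeric(cnt), half)
    if (res[["pairs"]] == 0) next
    val <- res[["total"]] / res[["pairs"]]
    n_eval <- n_eval + 1L
    if (val > best_cpe) {
      best_cpe <- val
      best <- cuts
    }
  }
  if (is.null(best)) stop("no candidate partition could be evaluated")
  list(cutpoints = cutpoint_set(best, labels = labels), cpe = best_cpe,
       n_candidates = n_eval)
}

# ---- clinical risk-classification rules engine -----------------------------

#' Load a clinical risk-classification rule set
#'
#' Rules are ordered first-match-wins predicates over cohort fields, kept
#' as JSON config so that trial-specific algorithms can be swapped in
#' without code changes. Each rule has a `label` and a `when` list of
#' clauses `{field, op, value}` with `op` one of `eq`, `ne`, `lt`, `le`,
#' `gt`, `ge`, `in`; all clauses must hold. An optional `default` label
#' applies when no rule matches.
#'
#' @param file JSON rules path; defaults to the shipped approximate
#'   classification (see [cog_clinical_rules()]).
#' @return object of class `clinical_rules`.
#' @export
read_clinical_rules <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = FALSE)
  structure(list(rules = cfg$rules, default = cfg$default,
                 name = cfg$name %||% "clinical rules"),
            class = "clinical_rules")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shipped approximate COG clinical risk classification
#'
#' An \emph{approximate}, config-driven stand-in for the trial risk
#' classification algorithms, built from the publicly described factors
#' (NCI risk group, favorable/unfavorable genetics, day-8/day-29 MRD
#' thresholds and CNS status). The exact trial algorithm tables are not
#' public; treat the resulting labels as illustrative.
#'
#' @return a `clinical_rules` object with labels SR-Fav, SR-Avg, SR-High,
#'   HR-Fav, HR, VHR.
#' @export
cog_clinical_rules <- function() {
  read_clinical_rules(system.file("extdata", "clinical_rules_synthetic.json",
                                  package = "mrdpi", mustWork = TRUE))
}

.apply_ops <- list(
  eq = function(x, v) x == v, ne = function(x, v) x != v,
  lt = function(x, v) x < v, le = function(x, v) x <= v,
  gt = function(x, v) x > v, ge = function(x, v) x >= v,
  `in` = function(x, v) x %in% unlist(v)
)

#' Classify patients with a clinical rule set
#'
#' Applies [read_clinical_rules()] rules to each record; the first
#' matching rule's label wins, falling back to the rule set's default. A
#' record whose evaluation touches a missing field, or that matches no
#' rule when no default exists, is an unclassified signal: an error by
#' default, or `NA` with `unclassified = "na"`.
#'
#' @param cohort patient table (see [cohort-schema]).
#' @param rules a `clinical_rules` object; default [cog_clinical_rules()].
#' @param unclassified `"error"` or `"na"`.
#' @return character vector of labels (with `NA` for unclassified records
#'   under `unclassified = "na"`).
#' @export
classify_cog_clinical <- function(cohort, rules = cog_clinical_rules(),
                                  unclassified = c("error", "na")) {
  unclassified <- match.arg(unclassified)
  stopifnot(inherits(rules, "clinical_rules"))
  one <- function(i) {
    for (r in rules$rules) {
      match_all <- TRUE
      for (cl in r$when) {
        if (!cl$field %in% names(cohort)) {
          stop("rule references unknown field '", cl$field, "'",
               call. = FALSE)
        }
        x <- cohort[[cl$field]][i]
        if (is.na(x)) {
          if (unclassified == "error") {
            stop("unclassified: record ", i, " is missing field '",
                 cl$field, "'", call. = FALSE)
          }
          return(NA_character_)
        }
        if (!.apply_ops[[cl$op]](x, cl$value)) { match_all <- FALSE; break }
      }
      if (match_all) return(r$label)
    }
    if (!is.null(rules$default)) return(rules$default)
    if (unclassified == "error") {
      stop("unclassified: no rule matches record ", i,
           " and no default label exists", call. = FALSE)
    }
    NA_character_
  }
  vapply(seq_len(nrow(cohort)), one, character(1))
}

#' Cross-tabulate two risk-group schemes with per-cell survival
#'
#' Contingency counts of two classification label vectors with row and
#' column totals, plus a per-cell Kaplan-Meier survival estimate (and
#' Greenwood SE) at a horizon. Cells with fewer than `min_n` patients
#' have their estimates suppressed (`NA`), counts are always reported.
#'
#' @param labels_a,labels_b equal-length label vectors (factor or
#'   character); `labels_a` forms the rows.
#' @param outcomes data frame with `time` and `event`, same length.
#' @param horizon estimate time in years; default 5.
#' @param min_n suppression threshold for per-cell estimates; default 25.
#' @return object of class `risk_crosstab`: `counts`, `estimate`, `se`
#'   matrices, `row_totals`, `col_totals`, `horizon`, `min_n`.
#' @export
crosstab_riskgroups <- function(labels_a, labels_b, outcomes, horizon = 5,
                                min_n = 25) {
  if (length(labels_a) != length(labels_b) ||
      length(labels_a) != nrow(outcomes)) {
    stop("label vectors and outcomes must have equal length", call. = FALSE)
  }
  fa <- factor(labels_a)
  fb <- factor(labels_b)
  counts <- table(fa, fb, dnn = NULL)
  est <- se <- matrix(NA_real_, nrow(counts), ncol(counts),
                      dimnames = dimnames(counts))
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      sel <- which(fa == rownames(counts)[i] & fb == colnames(counts)[j])
      if (length(sel) >= min_n) {
        km <- km_estimate(outcomes[sel, , drop = FALSE])
        at <- km_at_horizon(km, horizon, max_time = max(outcomes$time[sel]))
        est[i, j] <- at$estimate
        se[i, j] <- at$se
      }
    }
  }
  structure(list(counts = unclass(counts), estimate = est, se = se,
                 row_totals = rowSums(counts), col_totals = colSums(counts),
                 horizon = horizon, min_n = min_n),
            class = "risk_crosstab")
}

#' @export
print.risk_crosstab <- function(x, ...) {
  cat(sprintf("Risk-group cross-tabulation (KM at %g y; cells < %d suppressed)\n",
              x$horizon, x$min_n))
  cat("Counts:\n"); print(x$counts)
  cat("Survival estimates:\n"); print(round(x$estimate, 3))
  invisible(x)
}

#' Export a cross-tabulation as CSV
#'
#' Long-format rows `group_a, group_b, n, estimate, se`.
#'
#' @param x a `risk_crosstab`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_crosstab <- function(x, path) {
  stopifnot(inherits(x, "risk_crosstab"))
  long <- expand.grid(group_a = rownames(x$counts),
                      group_b = colnames(x$counts),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$n <- as.vector(x$counts)
  long$estimate <- as.vector(x$estimate)
  long$se <- as.vector(x$se)
  write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}
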