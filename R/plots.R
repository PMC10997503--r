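#' Kaplan-Meier curves by risk group
#'
#' Step-function survival curves for each group, with the number at risk
#' in the legend. Requires ggplot2.
#'
#' @param outcomes data frame with `time` and `event`.
#' @param groups factor of group labels, same length.
#' @return a ggplot object.
#' @export
plot_km_groups <- function(outcomes, groups) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_km_groups() requires the ggplot2 package")
  }
  groups <- factor(groups)
  dat <- do.call(rbind, lapply(levels(groups), function(g) {
    sel <- groups == g
    km <- km_estimate(outcomes[sel, , drop = FALSE])
    data.frame(group = sprintf("%s (n = %d)", g, sum(sel)),
               time = c(0, km$times), survival = c(1, km$survival))
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = time, y = survival, color = group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years from end of induction",
                  y = "Event-free probability", color = NULL) +
    ggplot2::theme_minimal()
}

#' Calibration plot
#'
#' Binned observed (Kaplan-Meier) versus mean predicted event-free
#' probability at the horizon, with the identity line. Requires ggplot2.
#'
#' @param curve result of [calibration_curve()].
#' @return a ggplot object.
#' @export
plot_calibration <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_calibration() requires the ggplot2 package")
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = mean_predicted,
                                      y = observed_km)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = n), alpha = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = observed_km - km_se,
                                        ymax = observed_km + km_se),
                           width = 0) +
    ggplot2::labs(x = "Mean predicted event-free probability",
                  y = "Observed (Kaplan-Meier)", size = "n") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("time", "survival", "group", "mean_predicted",
                         "observed_km", "km_se", "n"))
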