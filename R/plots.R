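# ggplot2 autoplot methods for the result types.

#' Plot a Kaplan-Meier curve
#'
#' Step-function survival curves, one per stratum when the curve was built
#' with [km_by_group()].
#'
#' @param object A `km_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- as_tibble(object)
  if (!"stratum" %in% names(df)) df$stratum <- "all"
  # prepend the (0, 1) anchor per stratum so curves start at full survival
  anchors <- dplyr::distinct(df, .data$stratum) |>
    dplyr::mutate(time = 0, survival = 1)
  df <- dplyr::bind_rows(anchors, df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   color = .data$stratum)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days from baseline imaging",
                  y = "Event-free probability", color = "Risk stratum") +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object An `mpisurv_roc` object from [roc_curve()] or
#'   [stratified_roc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mpisurv_roc
#' @export
autoplot.mpisurv_roc <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_path(linewidth = 0.8, color = "#2c5f8a") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      subtitle = sprintf("AUC = %.3f (%s)", roc_auc(object),
                         attr(object, "kind"))
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of subgroup hazard ratios
#'
#' @param data Output of [subgroup_forest()].
#' @return A ggplot object (log-scaled HR axis; non-estimable subgroups are
#'   dropped with a message).
#' @export
plot_forest <- function(data) {
  est <- dplyr::filter(data, .data$estimable)
  if (nrow(est) < nrow(data)) {
    message(sprintf("%d non-estimable subgroup(s) omitted from the forest",
                    nrow(data) - nrow(est)))
  }
  ggplot2::ggplot(est, ggplot2::aes(x = .data$hr, y = .data$subgroup)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a training-loss history
#'
#' @param scorer A trained `risk_scorer`.
#' @return A ggplot of the per-epoch mean loss per event.
#' @export
plot_training_history <- function(scorer) {
  if (is.null(scorer$history)) abort("scorer has no training history")
  ggplot2::ggplot(scorer$history,
                  ggplot2::aes(x = .data$epoch, y = .data$mean_loss)) +
    ggplot2::geom_line(color = "#2c5f8a") +
    ggplot2::labs(x = "Epoch", y = "Mean negative log partial likelihood per event") +
    ggplot2::theme_minimal()
}
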