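#' Plot nested cross-validation metrics
#'
#' Three-panel summary of an [nested_cv_evaluate()] result: cross-validated
#' R-squared, cross-validated MSE and relative efficiency per learner, with
#' a dashed reference line at the super learner's value in each panel.
#'
#' @param object An `sl_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sl_evaluation
#' @export
autoplot.sl_evaluation <- function(object, ...) {
  m <- object$metrics
  long <- tidyr::pivot_longer(
    m, c("cv_r2", "cv_mse", "rel_efficiency"),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric,
    levels = c("cv_r2", "cv_mse", "rel_efficiency"),
    labels = c("CV R²", "CV MSE ($²)", "Relative efficiency")
  )
  ref <- long[long$learner == "super_learner", c("metric", "value")]
  long <- long[long$learner != "super_learner", ]
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$learner, .data$value),
                                     y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL,
                  subtitle = "Dashed line: super learner") +
    ggplot2::theme_minimal()
}

#' Plot the residual distribution of the ensemble
#'
#' Histogram of out-of-fold residuals with extreme (robust-flagged)
#' residuals marked in the rug.
#'
#' @param report A [residual_report()] tibble.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_residuals <- function(report, bins = 60) {
  stopifnot(all(c("residual", "extreme") %in% names(report)))
  ggplot2::ggplot(report, ggplot2::aes(x = .data$residual)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_rug(data = report[report$extreme, , drop = FALSE],
                      colour = "red") +
    ggplot2::labs(x = "Residual: observed - predicted unprofitability ($)",
                  y = "Enrollees") +
    ggplot2::theme_minimal()
}
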