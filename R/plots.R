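# ggplot2 displays for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot category hours by segment for a cohort summary
#'
#' Bar chart of hours per physician per workday by clinical category,
#' split into during/outside scheduled clinic hours. Requires the summary
#' to have been built with actions (so the category table exists).
#'
#' @param object An `ehr_cohort_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ehr_cohort_summary <- function(object, ...) {
  ct <- object$category_table
  if (is.null(ct)) {
    stop_input("cohort summary has no category table; rebuild with actions")
  }
  df <- ct |>
    filter(.data$clinical_category != "total") |>
    select("clinical_category", during = "hours_during",
           outside = "hours_outside") |>
    tidyr::pivot_longer(c("during", "outside"), names_to = "segment",
                        values_to = "hours") |>
    mutate(clinical_category = factor(
      .data$clinical_category,
      levels = rev(category_levels(.data$clinical_category))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hours,
                                   y = .data$clinical_category,
                                   fill = .data$segment)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "hours per physician per workday", y = NULL,
                  fill = "segment",
                  title = "EHR time by action category") +
    ggplot2::theme_minimal()
}

#' Histogram of per-physician mean outside-hours
#'
#' Distribution across physicians of average EHR time outside scheduled
#' clinic hours per workday, with the high-user threshold marked.
#'
#' @param daily Daily summary from [summarize_daily()].
#' @param threshold_hours High-user threshold to mark (default 1.5; `NULL`
#'   to omit).
#' @param binwidth Histogram bin width in hours.
#' @return A ggplot.
#' @export
plot_outside_hours <- function(daily, threshold_hours = 1.5,
                               binwidth = 0.25) {
  pm <- physician_means(daily)
  p <- ggplot2::ggplot(pm, ggplot2::aes(x = .data$mean_outside)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::labs(
      x = "mean hours outside scheduled clinic hours per workday",
      y = "physicians",
      title = "EHR work outside scheduled clinic hours") +
    ggplot2::theme_minimal()
  if (!is.null(threshold_hours)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold_hours,
                                 linetype = "dashed")
  }
  p
}

#' Coefficient plot for a fitted EHR mixed model
#'
#' Fixed-effect estimates with approximate 95% intervals
#' (estimate +/- 1.96 SE); the intercept is omitted.
#'
#' @param object An `ehr_mixed_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ehr_mixed_fit <- function(object, ...) {
  cf <- object$coefficients |>
    filter(.data$term != "(Intercept)") |>
    mutate(lo = .data$estimate - 1.96 * .data$std_error,
           hi = .data$estimate + 1.96 * .data$std_error)
  ggplot2::ggplot(cf, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo,
                                          xmax = .data$hi)) +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL,
                  title = sprintf("%s EHR hours (%s aggregation)",
                                  object$spec$outcome,
                                  object$spec$aggregation)) +
    ggplot2::theme_minimal()
}
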