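# Cohort summary surface and the high-user subgroup.

#' Per-physician means over workdays
#'
#' Averages daily during/outside hours per physician with equal weight per
#' workday (rows with `workday = FALSE` are excluded from both numerator
#' and denominator).
#'
#' @param daily Daily summary from [summarize_daily()].
#' @return A tibble `physician_id`, `n_workdays`, `mean_during`,
#'   `mean_outside`.
#' @export
physician_means <- function(daily) {
  require_columns(daily, c("physician_id", "workday", "hours_during",
                           "hours_outside"), "daily")
  daily |>
    filter(.data$workday) |>
    group_by(.data$physician_id) |>
    summarise(n_workdays = n(),
              mean_during = mean(.data$hours_during),
              mean_outside = mean(.data$hours_outside),
              .groups = "drop")
}

#' Summarize a cohort of daily EHR-time records
#'
#' Builds the cohort reporting surface from per-physician-per-day records:
#' per-physician-per-workday means and SDs of during/outside hours (each
#' physician's workdays averaged first, then mean/SD taken across
#' physicians), pooled per-workday hours, the category table and top-action
#' table (when the underlying actions are supplied), administrative time
#' (when nominal clinic hours are supplied), and the high-user subgroup
#' (physicians whose mean outside-hours strictly exceed the threshold).
#'
#' @param daily Daily summary from [summarize_daily()].
#' @param actions Optional segmented, categorized actions; enables the
#'   category and top-action tables.
#' @param k_top Actions per category in the top-action table (default 3).
#' @param high_threshold_hours High-user threshold on mean outside hours
#'   per workday (default 1.5, strict `>`).
#' @param planned_clinic_hours Optional total nominal clinical hours in the
#'   period, for [admin_time()].
#' @param admin_fraction Administrative fraction of nominal hours
#'   (default 0.11).
#' @return An object of class `ehr_cohort_summary`; see [tidy()] and
#'   [glance()] methods, and [autoplot.ehr_cohort_summary()].
#' @export
summarize_cohort <- function(daily, actions = NULL, k_top = 3,
                             high_threshold_hours = 1.5,
                             planned_clinic_hours = NULL,
                             admin_fraction = 0.11) {
  pm <- physician_means(daily)
  n_workdays <- sum(daily$workday)
  wd <- filter(daily, .data$workday)
  hours <- tibble(
    segment = c("during", "outside"),
    mean = c(mean(pm$mean_during), mean(pm$mean_outside)),
    sd = c(sd(pm$mean_during), sd(pm$mean_outside)),
    median = c(stats::median(pm$mean_during),
               stats::median(pm$mean_outside)),
    min = c(min(pm$mean_during), min(pm$mean_outside)),
    max = c(max(pm$mean_during), max(pm$mean_outside))
  )
  pooled <- tibble(
    segment = c("during", "outside", "total"),
    hours_per_workday = c(sum(wd$hours_during), sum(wd$hours_outside),
                          sum(wd$hours_during) + sum(wd$hours_outside)) /
      n_workdays
  )
  pooled_total <- pooled$hours_per_workday[pooled$segment == "total"]
  pct_outside <- if (pooled_total > 0) {
    100 * pooled$hours_per_workday[pooled$segment == "outside"] /
      pooled_total
  } else NA_real_

  high_ids <- pm$physician_id[pm$mean_outside > high_threshold_hours]
  high <- list(
    threshold_hours = high_threshold_hours,
    ids = high_ids,
    n = length(high_ids),
    n_workdays = sum(pm$n_workdays[pm$physician_id %in% high_ids]),
    mean_outside = if (length(high_ids) > 0) {
      mean(pm$mean_outside[pm$physician_id %in% high_ids])
    } else NA_real_
  )

  out <- list(
    n_physicians = nrow(pm),
    n_workdays = n_workdays,
    physician_means = pm,
    hours = hours,
    pooled = pooled,
    pct_outside_of_total = pct_outside,
    category_table = if (!is.null(actions)) {
      category_table(actions, n_workdays)
    },
    top_actions = if (!is.null(actions)) {
      top_actions(actions, n_workdays, k = k_top)
    },
    admin_hours_per_workday = if (!is.null(planned_clinic_hours)) {
      admin_time(planned_clinic_hours, admin_fraction, n_workdays)
    },
    high_users = high
  )
  structure(out, class = "ehr_cohort_summary")
}

#' High users of the EHR outside scheduled clinic hours
#'
#' Selects physicians whose per-workday mean outside-hours strictly exceed
#' the threshold and returns the cohort summary restricted to that
#' subgroup. An empty subgroup yields `NULL` (with a message), not an
#' error.
#'
#' @inheritParams summarize_cohort
#' @param threshold_hours Selection threshold (default 1.5, strict `>`).
#' @return An `ehr_cohort_summary` for the subgroup, or `NULL` if no
#'   physician qualifies. The selected ids are in `$physician_means`.
#' @export
high_users <- function(daily, actions = NULL, threshold_hours = 1.5,
                       k_top = 3) {
  pm <- physician_means(daily)
  ids <- pm$physician_id[pm$mean_outside > threshold_hours]
  if (length(ids) == 0L) {
    inform("no physician exceeds the high-user threshold")
    return(NULL)
  }
  sub_daily <- filter(daily, .data$physician_id %in% ids)
  sub_actions <- if (!is.null(actions)) {
    filter(actions, .data$user_id %in% ids)
  }
  summarize_cohort(sub_daily, sub_actions, k_top = k_top,
                   high_threshold_hours = threshold_hours)
}

#' @exportS3Method base::print
print.ehr_cohort_summary <- function(x, ...) {
  cat("EHR cohort summary\n")
  cat(sprintf("  physicians: %d   physician-workdays: %d\n",
              x$n_physicians, x$n_workdays))
  h <- x$hours
  for (i in seq_len(nrow(h))) {
    cat(sprintf("  %-8s %4.1f h/workday (SD %.1f, median %.1f, range %.1f-%.1f)\n",
                h$segment[i], h$mean[i], h$sd[i], h$median[i], h$min[i],
                h$max[i]))
  }
  if (!is.na(x$pct_outside_of_total)) {
    cat(sprintf("  outside share of total EHR time: %.0f%%\n",
                x$pct_outside_of_total))
  }
  if (!is.null(x$admin_hours_per_workday)) {
    cat(sprintf("  administrative time: %.2f h/workday\n",
                x$admin_hours_per_workday))
  }
  cat(sprintf("  high users (> %.1f h outside): %d physician(s)\n",
              x$high_users$threshold_hours, x$high_users$n))
  if (!is.null(x$category_table)) {
    cat("  category table (h/physician/workday):\n")
    print(x$category_table)
  }
  invisible(x)
}

#' Tidy a cohort summary
#'
#' @param x An `ehr_cohort_summary`.
#' @param ... Unused.
#' @return The per-segment hour statistics as a tibble.
#' @export
tidy.ehr_cohort_summary <- function(x, ...) {
  x$hours
}

#' One-row overview of a cohort summary
#'
#' @param x An `ehr_cohort_summary`.
#' @param ... Unused.
#' @return A one-row tibble with cohort size, workdays, mean/SD hours, the
#'   outside share of total EHR time, and the high-user count.
#' @export
glance.ehr_cohort_summary <- function(x, ...) {
  h <- x$hours
  tibble(
    n_physicians = x$n_physicians,
    n_workdays = x$n_workdays,
    mean_during = h$mean[h$segment == "during"],
    sd_during = h$sd[h$segment == "during"],
    mean_outside = h$mean[h$segment == "outside"],
    sd_outside = h$sd[h$segment == "outside"],
    pct_outside_of_total = x$pct_outside_of_total,
    n_high_users = x$high_users$n
  )
}
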