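# aggregate: cohort filtering and the descriptive daily/cohort surfaces.

#' Apply cohort inclusion/exclusion rules
#'
#' Excludes physicians employed on contingent status, with zero clinical FTE,
#' or with no scheduled visits in the study period, in that order of
#' precedence. The returned roster carries an `eligible` flag and an
#' `exclusion_reason` (`NA` for eligible physicians); the tally by reason is
#' attached as attribute `exclusions`.
#'
#' @param roster Physician roster (see [read_roster()]).
#' @param visits Scheduled visits; physicians absent from it are excluded
#'   for having no visits.
#' @return The roster tibble with `eligible` and `exclusion_reason` columns.
#' @export
filter_cohort <- function(roster, visits) {
  validate_roster(roster)
  require_columns(visits, "physician_id", "visits")
  has_visits <- roster$physician_id %in% visits$physician_id
  reason <- rep(NA_character_, nrow(roster))
  reason[!has_visits] <- "no_visits"
  reason[roster$cfte == 0] <- "zero_cfte"
  reason[roster$employment_status == "contingent"] <- "contingent"
  out <- roster
  out$eligible <- is.na(reason)
  out$exclusion_reason <- reason
  tally <- table(factor(reason, levels = c("contingent", "zero_cfte",
                                           "no_visits")))
  attr(out, "exclusions") <- as.list(tally)
  out
}

#' Eligible physician ids from a filtered roster
#'
#' @param cohort Output of [filter_cohort()].
#' @return Character vector of eligible physician ids.
#' @export
eligible_ids <- function(cohort) {
  require_columns(cohort, c("physician_id", "eligible"), "cohort")
  cohort$physician_id[cohort$eligible]
}

#' Summarize EHR time per physician per day
#'
#' Produces one row per (physician, date) that has at least one retained
#' access-log event or at least one scheduled visit — days with neither do
#' not exist in the summary. The `workday` flag marks rows entering per-
#' workday denominators, under a configurable rule:
#' `"either"` (default; any row qualifies), `"events"` (>= 1 retained
#' event), `"visits"` (>= 1 scheduled visit).
#'
#' @param actions Segmented, categorized actions ([segment_actions()],
#'   [categorize_actions()]).
#' @param visits Optional visits tibble; supplies visit-only days and the
#'   visit side of the workday rule.
#' @param workday Workday rule, see above.
#' @return A tibble with `physician_id`, `date`, `has_events`,
#'   `has_visits`, `workday`, `hours_during`, `hours_outside`, `n_during`,
#'   `n_outside`.
#' @export
summarize_daily <- function(actions, visits = NULL,
                            workday = c("either", "events", "visits")) {
  workday <- match.arg(workday)
  require_columns(actions, c("user_id", "date", "during_s", "outside_s",
                             "segment"), "actions")
  ev <- actions |>
    group_by(physician_id = .data$user_id, date = .data$date) |>
    summarise(hours_during = sum(.data$during_s) / 3600,
              hours_outside = sum(.data$outside_s) / 3600,
              n_during = sum(.data$segment == "during"),
              n_outside = sum(.data$segment == "outside"),
              .groups = "drop") |>
    mutate(has_events = TRUE)
  if (!is.null(visits) && nrow(visits) > 0) {
    vd <- visits |>
      mutate(date = clinic_date(.data$start)) |>
      distinct(.data$physician_id, .data$date) |>
      mutate(has_visits = TRUE)
  } else {
    vd <- tibble(physician_id = character(0),
                 date = as.Date(character(0)), has_visits = logical(0))
  }
  out <- dplyr::full_join(ev, vd, by = c("physician_id", "date")) |>
    mutate(has_events = !is.na(.data$has_events),
           has_visits = !is.na(.data$has_visits),
           across(c("hours_during", "hours_outside"),
                  ~ ifelse(is.na(.x), 0, .x)),
           across(c("n_during", "n_outside"),
                  ~ ifelse(is.na(.x), 0L, as.integer(.x))))
  out$workday <- switch(workday,
                        either = out$has_events | out$has_visits,
                        events = out$has_events,
                        visits = out$has_visits)
  out |>
    select("physician_id", "date", "has_events", "has_visits", "workday",
           "hours_during", "hours_outside", "n_during", "n_outside") |>
    arrange(.data$physician_id, .data$date)
}

#' Per-day hours and counts by clinical category
#'
#' Long companion to [summarize_daily()]: one row per
#' (physician, date, clinical category) with hours and counts by segment.
#' Within each (physician, date), category hours sum to the daily totals.
#'
#' @inheritParams summarize_daily
#' @return A tibble keyed by `physician_id`, `date`, `clinical_category`.
#' @export
summarize_daily_categories <- function(actions) {
  require_columns(actions, c("user_id", "date", "clinical_category",
                             "during_s", "outside_s", "segment"), "actions")
  actions |>
    group_by(physician_id = .data$user_id, date = .data$date,
             clinical_category = .data$clinical_category) |>
    summarise(hours_during = sum(.data$during_s) / 3600,
              hours_outside = sum(.data$outside_s) / 3600,
              n_during = sum(.data$segment == "during"),
              n_outside = sum(.data$segment == "outside"),
              .groups = "drop") |>
    arrange(.data$physician_id, .data$date, .data$clinical_category)
}

category_levels <- function(x) {
  union(CLINICAL_CATEGORIES, unique(x))
}

#' Hours per physician per workday by action category
#'
#' Pools all action time over the cohort's physician-workdays and reports,
#' per clinical category, hours per physician per workday spent during and
#' outside scheduled clinic hours and in total, with each column's percent
#' share. Hours print to 2 decimals and percents to integers; the total row
#' is computed on unrounded values and then rounded, so a rounded column may
#' differ from its printed total by one unit in the last place.
#'
#' @param actions Segmented, categorized actions.
#' @param n_workdays Number of physician-workdays (the denominator), e.g.
#'   from [summarize_daily()].
#' @return A tibble with one row per clinical category plus a `total` row:
#'   `clinical_category`, `hours_during`, `pct_during`, `hours_outside`,
#'   `pct_outside`, `hours_total`, `pct_total`.
#' @export
category_table <- function(actions, n_workdays) {
  require_columns(actions, c("clinical_category", "during_s", "outside_s"),
                  "actions")
  if (!is_scalar_number(n_workdays) || n_workdays <= 0) {
    stop_input("n_workdays must be a single positive number")
  }
  per_cat <- actions |>
    mutate(clinical_category = factor(
      .data$clinical_category,
      levels = category_levels(.data$clinical_category))) |>
    group_by(.data$clinical_category, .drop = FALSE) |>
    summarise(hours_during = sum(.data$during_s) / 3600 / n_workdays,
              hours_outside = sum(.data$outside_s) / 3600 / n_workdays,
              .groups = "drop") |>
    mutate(hours_total = .data$hours_during + .data$hours_outside)
  tot <- per_cat |>
    summarise(across(c("hours_during", "hours_outside", "hours_total"),
                     sum)) |>
    mutate(clinical_category = "total")
  pct_of <- function(x, total) {
    if (total <= 0) rep(NA_real_, length(x)) else 100 * x / total
  }
  bind_rows(per_cat |>
              mutate(clinical_category =
                       as.character(.data$clinical_category)),
            tot) |>
    mutate(pct_during = round(pct_of(.data$hours_during,
                                     tot$hours_during)),
           pct_outside = round(pct_of(.data$hours_outside,
                                      tot$hours_outside)),
           pct_total = round(pct_of(.data$hours_total, tot$hours_total)),
           across(c("hours_during", "hours_outside", "hours_total"),
                  ~ round(.x, 2))) |>
    select("clinical_category", "hours_during", "pct_during",
           "hours_outside", "pct_outside", "hours_total", "pct_total")
}

#' Most frequent actions per category in a segment
#'
#' For each of the four clinical categories (review, documentation, inbox,
#' orders), reports the `k` most frequent actions whose primary segment is
#' `segment`, as frequency (integer) and minutes (1 decimal) per physician
#' per workday, with a grand-total row over the selected actions. Totals
#' are computed on unrounded values, then rounded. Frequency ties break by
#' larger total minutes, then lexicographic action code.
#'
#' @param actions Segmented, categorized actions.
#' @param n_workdays Physician-workday denominator.
#' @param k Actions per category (default 3).
#' @param segment `"outside"` (default) or `"during"` — selection is by
#'   each action's primary segment label.
#' @return A tibble `clinical_category`, `action_code`, `freq`, `minutes`,
#'   ending with a `total` row.
#' @export
top_actions <- function(actions, n_workdays, k = 3,
                        segment = c("outside", "during")) {
  segment <- match.arg(segment)
  require_columns(actions, c("clinical_category", "action_code",
                             "duration_s", "segment"), "actions")
  if (!is_scalar_number(n_workdays) || n_workdays <= 0) {
    stop_input("n_workdays must be a single positive number")
  }
  clinical4 <- c("review", "documentation", "inbox", "orders")
  sel <- actions |>
    filter(.data$segment == !!segment,
           .data$clinical_category %in% clinical4) |>
    group_by(.data$clinical_category, .data$action_code) |>
    summarise(freq = n() / n_workdays,
              minutes = sum(.data$duration_s) / 60 / n_workdays,
              .groups = "drop_last") |>
    arrange(desc(.data$freq), desc(.data$minutes), .data$action_code,
            .by_group = TRUE) |>
    slice_head(n = k) |>
    ungroup() |>
    mutate(clinical_category = factor(.data$clinical_category,
                                      levels = clinical4)) |>
    arrange(.data$clinical_category) |>
    mutate(clinical_category = as.character(.data$clinical_category))
  tot <- tibble(clinical_category = "total", action_code = NA_character_,
                freq = sum(sel$freq), minutes = sum(sel$minutes))
  bind_rows(sel, tot) |>
    mutate(freq = round(.data$freq), minutes = round(.data$minutes, 1))
}

#' Administrative time per workday
#'
#' Administrative time — schedule time reserved for notes, inbox work, and
#' other patient-care administration — is estimated as a fixed fraction of
#' the nominal clinical hours over the study period, spread over the
#' physician-workdays.
#'
#' @param planned_clinic_hours Total nominal clinical hours in the period.
#' @param admin_fraction Fraction of nominal hours that is administrative
#'   time (default 0.11).
#' @param n_workdays Number of physician-workdays.
#' @return Hours of administrative time per physician-workday.
#' @export
#' @examples
#' admin_time(100, 0.11, 22) # 0.5
admin_time <- function(planned_clinic_hours, admin_fraction = 0.11,
                       n_workdays) {
  if (!is_scalar_number(planned_clinic_hours) || planned_clinic_hours < 0) {
    stop_input("planned_clinic_hours must be a single number >= 0")
  }
  if (!is_scalar_number(admin_fraction) || admin_fraction < 0) {
    stop_input("admin_fraction must be a single number >= 0")
  }
  if (!is_scalar_number(n_workdays) || n_workdays <= 0) {
    stop_input("n_workdays must be a single positive number")
  }
  admin_fraction * planned_clinic_hours / n_workdays
}
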