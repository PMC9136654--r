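# sessionize: per-action access time from inter-event deltas, idle removal.

#' Estimate per-action access time from inter-event gaps
#'
#' Access time for an action is defined as the gap between that audit-log
#' entry and the same user's next entry; a user's final event has duration
#' zero (it has no successor). Gaps are computed within user only, never
#' across users, and are computed across day boundaries — overnight gaps are
#' then removed by the idle filter ([filter_idle()]), not here.
#'
#' @param events Access-log tibble (`user_id`, `timestamp`, `action_code`,
#'   optionally `source`), sorted by user and timestamp as produced by
#'   [read_access_log()]. Unsorted input is an error.
#' @return The input with a `duration_s` column (seconds, >= 0) appended.
#' @export
#' @examples
#' events <- tibble::tibble(
#'   user_id = "a",
#'   timestamp = as.POSIXct("2019-09-03 08:00:00", tz = "UTC") +
#'     c(0, 100, 200),
#'   action_code = "AC1"
#' )
#' estimate_access_time(events)$duration_s # 100 100 0
estimate_access_time <- function(events) {
  require_columns(events, c("user_id", "timestamp", "action_code"), "events")
  events <- as_tibble(events)
  if (nrow(events) == 0L) {
    events$duration_s <- numeric(0)
    return(events)
  }
  t_num <- as.numeric(events$timestamp)
  same_user <- events$user_id[-1L] == events$user_id[-nrow(events)]
  if (is.unsorted(events$user_id) ||
      any(same_user & diff(t_num) < 0)) {
    stop_input("events must be sorted by (user_id, timestamp); see read_access_log()")
  }
  nxt <- c(t_num[-1L], NA_real_)
  dur <- nxt - t_num
  dur[c(!same_user, TRUE)] <- 0 # last event per user has no successor
  events$duration_s <- dur
  events
}

#' Remove idle gaps from timed actions
#'
#' Gaps longer than the idle cutoff are treated as time away from the EHR,
#' not active use. Removal is strict: an action whose duration *exceeds* the
#' cutoff is removed; a duration exactly equal to the cutoff is retained.
#' Under the default policy the action is dropped from both time totals and
#' frequency counts; `policy = "zero_duration"` instead keeps the event with
#' duration zero so that it still counts in frequency surfaces.
#'
#' @param actions Tibble with a `duration_s` column, as produced by
#'   [estimate_access_time()].
#' @param cutoff_min Idle cutoff in minutes (default 15; must be > 0;
#'   `Inf` disables filtering).
#' @param policy `"remove"` (default) or `"zero_duration"`.
#' @return The filtered tibble; attributes `n_removed` and
#'   `removed_seconds` record the removal tally.
#' @export
filter_idle <- function(actions, cutoff_min = 15,
                        policy = c("remove", "zero_duration")) {
  policy <- match.arg(policy)
  require_columns(actions, "duration_s", "actions")
  if (!is_scalar_number(cutoff_min) && !identical(cutoff_min, Inf)) {
    stop_input("cutoff_min must be a single positive number")
  }
  if (cutoff_min <= 0) stop_input("cutoff_min must be > 0")
  cutoff_s <- cutoff_min * 60
  idle <- actions$duration_s > cutoff_s
  removed_s <- sum(actions$duration_s[idle])
  out <- if (policy == "remove") {
    actions[!idle, , drop = FALSE]
  } else {
    actions$duration_s[idle] <- 0
    actions
  }
  attr(out, "n_removed") <- sum(idle)
  attr(out, "removed_seconds") <- removed_s
  out
}
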