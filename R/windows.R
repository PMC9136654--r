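# windows: scheduled-clinic-hour window construction and during/outside
# decomposition of action durations.
#
# Intervals are half-open [start, end): an event at an interval's exact end
# is outside, which eliminates double counting at shared boundaries.

#' Build scheduled-clinic-hour windows from visits
#'
#' Each physician's scheduled clinic hours on a day are the union of
#' `[visit_start - margin, visit_end + margin)` over that day's visits, with
#' overlapping or touching expansions merged, so back-to-back visits produce
#' one contiguous window. The margin captures preparatory and closing work
#' around a run of consecutive visits. A window that crosses midnight (an
#' evening clinic plus margin) belongs to the date of its earliest
#' generating visit.
#'
#' @param visits Visits tibble (`physician_id`, `start`, `end`), validated
#'   per [read_visits()].
#' @param margin_min Margin in minutes added before and after each visit
#'   (default 30; must be >= 0).
#' @return A tibble with one row per merged interval: `physician_id`,
#'   `date`, `window_start`, `window_end`.
#' @export
#' @examples
#' v <- tibble::tibble(
#'   physician_id = "p1",
#'   start = as.POSIXct(c("2019-09-03 09:00", "2019-09-03 09:20"), tz = "UTC"),
#'   end = as.POSIXct(c("2019-09-03 09:20", "2019-09-03 09:40"), tz = "UTC")
#' )
#' build_clinic_windows(v) # one merged window 08:30-10:10
build_clinic_windows <- function(visits, margin_min = 30) {
  validate_visits(visits)
  if (!is_scalar_number(margin_min) || margin_min < 0) {
    stop_input("margin_min must be a single number >= 0")
  }
  if (nrow(visits) == 0L) {
    return(tibble(physician_id = character(0),
                  date = as.Date(character(0)),
                  window_start = as.POSIXct(character(0), tz = EHR_TZ),
                  window_end = as.POSIXct(character(0), tz = EHR_TZ)))
  }
  m <- margin_min * 60
  v <- visits |>
    mutate(w_start = as.numeric(.data$start) - m,
           w_end = as.numeric(.data$end) + m,
           visit_date = clinic_date(.data$start)) |>
    arrange(.data$physician_id, .data$w_start, .data$w_end)
  v <- v |>
    group_by(.data$physician_id) |>
    mutate(run_end = cummax(.data$w_end),
           new_block = .data$w_start > dplyr::lag(.data$run_end,
                                                  default = -Inf),
           block = cumsum(.data$new_block)) |>
    group_by(.data$physician_id, .data$block) |>
    summarise(date = min(.data$visit_date),
              window_start = min(.data$w_start),
              window_end = max(.data$w_end),
              .groups = "drop") |>
    select(-"block")
  v |>
    mutate(window_start = as.POSIXct(.data$window_start,
                                     origin = "1970-01-01", tz = EHR_TZ),
           window_end = as.POSIXct(.data$window_end,
                                   origin = "1970-01-01", tz = EHR_TZ)) |>
    arrange(.data$physician_id, .data$window_start)
}

# Per-physician cumulative in-window time function.
# Returns, for sorted numeric times t, total window time strictly before t.
window_cum_before <- function(t, starts, ends) {
  if (length(starts) == 0L) return(numeric(length(t)))
  cumlen <- c(0, cumsum(ends - starts))
  pos <- findInterval(t, starts)
  inside <- pos > 0L
  out <- numeric(length(t))
  p <- pos[inside]
  out[inside] <- cumlen[p] + pmin(t[inside], ends[p]) - starts[p]
  # pmin handles t past the interval end; clamp against negative fuzz
  pmax(out, 0)
}

#' Decompose action durations into during/outside segments
#'
#' Each timed action occupies the half-open interval
#' `[timestamp, timestamp + duration)`. Under the default
#' `straddle = "split"` policy that occupancy is intersected with the
#' physician's clinic windows: `during_s` is the total intersection length
#' and `outside_s` the remainder, so `during_s + outside_s` always equals
#' the duration exactly. Under `straddle = "start"` the whole duration is
#' assigned to the segment containing the start timestamp. In both cases the
#' integer-valued *primary segment* label (used by frequency counts) is the
#' segment containing the start timestamp.
#'
#' @param actions Timed actions (`user_id`, `timestamp`, `duration_s`, ...),
#'   as from [estimate_access_time()] / [filter_idle()]. The `user_id` is
#'   matched against the windows' `physician_id`.
#' @param windows Clinic windows from [build_clinic_windows()]. Users with
#'   no windows have all time outside.
#' @param straddle `"split"` (default, proportional by clock time) or
#'   `"start"`.
#' @return The input with columns `during_s`, `outside_s`, and `segment`
#'   (`"during"`/`"outside"`, the primary label) appended, plus a `date`
#'   column (calendar day of the start timestamp).
#' @export
segment_actions <- function(actions, windows,
                            straddle = c("split", "start")) {
  straddle <- match.arg(straddle)
  require_columns(actions, c("user_id", "timestamp", "duration_s"),
                  "actions")
  require_columns(windows, c("physician_id", "window_start", "window_end"),
                  "windows")
  actions <- as_tibble(actions)
  n <- nrow(actions)
  t0 <- as.numeric(actions$timestamp)
  dur <- actions$duration_s
  if (any(dur < 0)) stop_input("durations must be >= 0")
  during <- numeric(n)
  start_in <- logical(n)

  idx_by_user <- split(seq_len(n), actions$user_id)
  w_by_user <- split(windows[c("window_start", "window_end")],
                     windows$physician_id)
  for (uid in names(idx_by_user)) {
    idx <- idx_by_user[[uid]]
    w <- w_by_user[[uid]]
    if (is.null(w) || nrow(w) == 0L) next
    ws <- sort(as.numeric(w$window_start))
    we <- as.numeric(w$window_end)[order(as.numeric(w$window_start))]
    # merge any overlap across days so the cumulative function is valid
    if (length(ws) > 1L) {
      keep_start <- c(TRUE, ws[-1L] > cummax(we[-length(we)]))
      blk <- cumsum(keep_start)
      ws <- as.numeric(tapply(ws, blk, min))
      we <- as.numeric(tapply(cummax(we), blk, max))
    }
    f0 <- window_cum_before(t0[idx], ws, we)
    f1 <- window_cum_before(t0[idx] + dur[idx], ws, we)
    during[idx] <- pmin(pmax(f1 - f0, 0), dur[idx])
    pos <- findInterval(t0[idx], ws)
    start_in[idx] <- pos > 0L & t0[idx] < we[pmax(pos, 1L)]
  }
  if (straddle == "start") {
    during <- ifelse(start_in, dur, 0)
  }
  actions$during_s <- during
  actions$outside_s <- dur - during
  actions$segment <- ifelse(start_in, "during", "outside")
  actions$date <- clinic_date(actions$timestamp)
  actions
}
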