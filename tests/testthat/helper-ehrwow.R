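# Shared fixtures and the independent brute-force oracle.

TZ <- "UTC"

ts <- function(x) as.POSIXct(x, tz = TZ)

# events tibble from numeric offsets (seconds) relative to a base instant
events_at <- function(offsets, user = "u1", code = "REV_001",
                      base = "2019-09-03 08:00:00") {
  tibble::tibble(user_id = user,
                 timestamp = ts(base) + offsets,
                 action_code = code)
}

windows_at <- function(starts, ends, user = "u1",
                       base = "2019-09-03 00:00:00") {
  tibble::tibble(physician_id = user,
                 date = as.Date(substr(base, 1, 10)),
                 window_start = ts(base) + starts,
                 window_end = ts(base) + ends)
}

# Independent second-level oracle: assigns each whole second of the
# occupancy [t0, t0 + dur) to during/outside by point-in-interval testing
# against half-open windows. Integer seconds only.
oracle_during_seconds <- function(t0, dur, win_starts, win_ends) {
  if (dur == 0) return(0)
  secs <- t0 + seq_len(dur) - 1
  inside <- vapply(secs, function(s) {
    any(win_starts <= s & s < win_ends)
  }, logical(1))
  sum(inside)
}

# random merged integer window set within [0, span)
random_windows <- function(n_win, span) {
  if (n_win == 0) return(list(starts = numeric(0), ends = numeric(0)))
  cuts <- sort(sample.int(span, 2 * n_win))
  starts <- cuts[seq(1, length(cuts), by = 2)]
  ends <- cuts[seq(2, length(cuts), by = 2)]
  keep <- ends > starts
  list(starts = starts[keep], ends = ends[keep])
}

# a tiny roster consistent with validate_roster()
make_roster <- function(ids, status = "regular", cfte = 0.5) {
  n <- length(ids)
  tibble::tibble(physician_id = ids,
                 age = 45, sex = rep_len(c("female", "male"), n),
                 service_years = 10, fte = 0.8,
                 cfte = rep_len(cfte, n),
                 employment_status = rep_len(status, n))
}

# segmented + categorized action rows built directly (bypasses the event
# layer) for aggregation worked examples
make_segmented <- function(df, user = "p1", date = as.Date("2019-09-03")) {
  defaults <- tibble::tibble(
    user_id = user, date = date,
    timestamp = ts(paste(date, "08:00:00")),
    action_code = "REV_001", duration_s = 0, during_s = 0, outside_s = 0,
    segment = "during", clinical_category = "review",
    conceptual_category = "data_review"
  )
  out <- df
  for (nm in names(defaults)) {
    if (!nm %in% names(out)) out[[nm]] <- defaults[[nm]][1]
  }
  out$duration_s <- out$during_s + out$outside_s
  out
}

# Table-2-shaped per-workday category hours (exact printed cell values)
TABLE2_DURING <- c(review = 3.13, documentation = 0.28, inbox = 0.52,
                   orders = 0.12, login = 0.03, logout = 0.28)
TABLE2_OUTSIDE <- c(review = 0.59, documentation = 0.05, inbox = 0.08,
                    orders = 0.01, login = 0.01, logout = 0.02)

table2_actions <- function() {
  make_segmented(tibble::tibble(
    clinical_category = rep(names(TABLE2_DURING), 2),
    during_s = c(TABLE2_DURING, rep(0, 6)) * 3600,
    outside_s = c(rep(0, 6), TABLE2_OUTSIDE) * 3600,
    segment = rep(c("during", "outside"), each = 6)
  ))
}

# Table-3-shaped outside-hours top actions for one physician-workday:
# (category, code, frequency, total minutes)
TABLE3_ROWS <- tibble::tribble(
  ~clinical_category, ~action_code, ~freq, ~minutes,
  "review", "patient_data_viewed", 28, 12.7,
  "review", "encounter_data_viewed", 4, 3.5,
  "review", "clinical_notes_viewed", 4, 3.2,
  "documentation", "visit_template_used", 15, 1.1,
  "documentation", "clinical_note_signed", 2, 0.4,
  "documentation", "encounter_dx_entered", 2, 0.3,
  "inbox", "inbox_message_viewed", 8, 2.2,
  "inbox", "inbox_message_created", 3, 0.7,
  "inbox", "inbox_folder_loaded", 3, 0.7,
  "orders", "outpatient_order_set", 3, 0.2,
  "orders", "order_list_changed", 1, 0.2,
  "orders", "length_of_stay_entered", 1, 0.2
)

table3_actions <- function() {
  rows <- TABLE3_ROWS[rep(seq_len(nrow(TABLE3_ROWS)), TABLE3_ROWS$freq), ]
  make_segmented(tibble::tibble(
    clinical_category = rows$clinical_category,
    action_code = rows$action_code,
    outside_s = rows$minutes * 60 / rows$freq,
    segment = "outside"
  ))
}

# small fast simulation config for unit tests
small_config <- function(seed = 7L, ...) {
  sim_config(n_physicians = 6, gap_mean_s = 60, seed = seed, ...)
}

quiet_sim <- function(config) suppressWarnings(simulate_cohort(config))
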