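# io_schemas: strict readers/writers for the four input CSV schemas.
#
# CSV dialect is fixed: comma-separated, UTF-8, header required, RFC-4180
# quoting. Timestamps are zone-naive ISO-8601 at second resolution and are
# interpreted on a single local clinic clock.

read_schema_csv <- function(path, what) {
  if (!file.exists(path)) {
    stop_input("%s file not found: %s", what, path)
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  as_tibble(df)
}

# Map data-row index -> physical file line (header is line 1).
row_lines <- function(i) i + 1L

parse_time_column <- function(x, what, column) {
  parsed <- parse_clinic_time(x)
  bad <- which(is.na(parsed) & !is.na(x))
  if (length(bad) > 0) {
    stop_input(
      "%s: unparsable %s at line(s) %s (first offending value: '%s')",
      what, column, paste(row_lines(head(bad, 5L)), collapse = ", "),
      x[bad[1L]]
    )
  }
  if (anyNA(parsed)) {
    bad <- which(is.na(parsed))
    stop_input("%s: empty %s at line(s) %s", what, column,
               paste(row_lines(head(bad, 5L)), collapse = ", "))
  }
  parsed
}

#' Read an EHR access log
#'
#' Reads a CSV of raw audit-log events, one row per discrete time-stamped
#' user action. Required columns: `user_id`, `timestamp` (ISO-8601, second
#' resolution, local clinic clock), `action_code`; an optional `source`
#' column (device/module tag) is carried through. Events are returned sorted
#' by user and timestamp; ties keep file order, so equal-timestamp events
#' remain in their original relative order.
#'
#' @param path Path to the access-log CSV.
#' @return A tibble with columns `user_id`, `timestamp` (POSIXct),
#'   `action_code`, and `source` (character, `NA` when absent).
#' @export
read_access_log <- function(path) {
  df <- read_schema_csv(path, "access log")
  require_columns(df, c("user_id", "timestamp", "action_code"), "access log")
  ts <- parse_time_column(df$timestamp, "access log", "timestamp")
  bad <- which(is.na(df$action_code) | !nzchar(df$action_code))
  if (length(bad) > 0) {
    stop_input("access log: empty action_code at line(s) %s",
               paste(row_lines(head(bad, 5L)), collapse = ", "))
  }
  out <- tibble(
    user_id = df$user_id,
    timestamp = ts,
    action_code = df$action_code,
    source = if ("source" %in% names(df)) df$source else NA_character_
  )
  out <- out[order(out$user_id, out$timestamp), , drop = FALSE]
  out
}

#' Read scheduled patient visits
#'
#' Reads a CSV of scheduled visits with columns `physician_id`, `start`,
#' `end` (ISO-8601 local clinic times). Every visit must satisfy
#' `start < end` and last at most 24 hours.
#'
#' @param path Path to the visits CSV.
#' @return A tibble with columns `physician_id`, `start`, `end` (POSIXct).
#' @export
read_visits <- function(path) {
  df <- read_schema_csv(path, "visits")
  require_columns(df, c("physician_id", "start", "end"), "visits")
  start <- parse_time_column(df$start, "visits", "start")
  end <- parse_time_column(df$end, "visits", "end")
  out <- tibble(physician_id = df$physician_id, start = start, end = end)
  validate_visits(out)
  out[order(out$physician_id, out$start), , drop = FALSE]
}

#' Validate a visits table
#'
#' @param visits Tibble with `physician_id`, `start`, `end`.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_visits <- function(visits) {
  require_columns(visits, c("physician_id", "start", "end"), "visits")
  bad <- which(as.numeric(visits$end) <= as.numeric(visits$start))
  if (length(bad) > 0) {
    stop_input("visits: end <= start at line(s) %s",
               paste(row_lines(head(bad, 5L)), collapse = ", "))
  }
  too_long <- which(as.numeric(visits$end) - as.numeric(visits$start) >
                      24 * 3600)
  if (length(too_long) > 0) {
    stop_input("visits: duration exceeds 24 h at line(s) %s",
               paste(row_lines(head(too_long, 5L)), collapse = ", "))
  }
  invisible(visits)
}

#' Read a physician roster
#'
#' Reads a CSV with columns `physician_id`, `age` (years), `sex`
#' (`male`/`female`), `service_years`, `fte`, `cfte`, `employment_status`
#' (`regular`/`contingent`). Enforces `0 <= cfte <= fte <= 1`, `age > 0`,
#' `service_years >= 0`.
#'
#' @param path Path to the roster CSV.
#' @return A tibble of physician records.
#' @export
read_roster <- function(path) {
  df <- read_schema_csv(path, "roster")
  cols <- c("physician_id", "age", "sex", "service_years", "fte", "cfte",
            "employment_status")
  require_columns(df, cols, "roster")
  out <- tibble(
    physician_id = df$physician_id,
    age = as.numeric(df$age),
    sex = df$sex,
    service_years = as.numeric(df$service_years),
    fte = as.numeric(df$fte),
    cfte = as.numeric(df$cfte),
    employment_status = df$employment_status
  )
  validate_roster(out)
  out
}

#' Validate a physician roster
#'
#' @param roster Tibble of physician records.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_roster <- function(roster) {
  cols <- c("physician_id", "age", "sex", "service_years", "fte", "cfte",
            "employment_status")
  require_columns(roster, cols, "roster")
  check <- function(bad, msg) {
    bad <- which(bad)
    if (length(bad) > 0) {
      stop_input("roster: %s at line(s) %s", msg,
                 paste(row_lines(head(bad, 5L)), collapse = ", "))
    }
  }
  check(!roster$sex %in% c("male", "female"), "sex must be male/female")
  check(!roster$employment_status %in% c("regular", "contingent"),
        "employment_status must be regular/contingent")
  check(is.na(roster$age) | roster$age <= 0, "age must be > 0")
  check(is.na(roster$service_years) | roster$service_years < 0,
        "service_years must be >= 0")
  check(is.na(roster$fte) | roster$fte < 0 | roster$fte > 1,
        "fte must be in [0, 1]")
  check(is.na(roster$cfte) | roster$cfte < 0, "cfte must be >= 0")
  check(roster$cfte > roster$fte, "cfte must not exceed fte")
  check(duplicated(roster$physician_id), "duplicate physician_id")
  invisible(roster)
}

#' Read an action-category map
#'
#' Reads a CSV with columns `action_code`, `clinical_category` (one of
#' `review`, `documentation`, `inbox`, `orders`, `login`, `logout`) and
#' optionally `conceptual_category`. The conceptual category is always
#' recomputed from the fixed clinical-to-conceptual alignment
#' ([conceptual_alignment()]); if the file supplies a conflicting conceptual
#' label, reading fails. Duplicate `action_code` rows with conflicting
#' clinical categories are rejected.
#'
#' @param path Path to the action-map CSV.
#' @return A tibble with columns `action_code`, `clinical_category`,
#'   `conceptual_category`.
#' @export
read_action_map <- function(path) {
  df <- read_schema_csv(path, "action map")
  require_columns(df, c("action_code", "clinical_category"), "action map")
  bad <- which(!df$clinical_category %in% CLINICAL_CATEGORIES)
  if (length(bad) > 0) {
    stop_input("action map: unknown clinical_category '%s' at line %s",
               df$clinical_category[bad[1L]], row_lines(bad[1L]))
  }
  dup <- df |>
    distinct(.data$action_code, .data$clinical_category) |>
    count(.data$action_code) |>
    filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    stop_input("action map: conflicting categories for action_code(s): %s",
               paste(head(dup$action_code, 5L), collapse = ", "))
  }
  out <- df |>
    distinct(.data$action_code, .data$clinical_category) |>
    mutate(conceptual_category =
             unname(CONCEPTUAL_MAP[.data$clinical_category]))
  if ("conceptual_category" %in% names(df)) {
    supplied <- distinct(df, .data$action_code,
                         supplied = .data$conceptual_category)
    chk <- left_join(out, supplied, by = "action_code")
    bad <- which(!is.na(chk$supplied) &
                   chk$supplied != chk$conceptual_category)
    if (length(bad) > 0) {
      stop_input(
        "action map: conceptual_category for '%s' conflicts with the fixed clinical-to-conceptual alignment",
        chk$action_code[bad[1L]])
    }
  }
  as_tibble(out)
}

#' Write pipeline inputs or outputs as CSV
#'
#' Writes a tibble with the package's fixed CSV dialect (comma-separated,
#' UTF-8, header, RFC-4180 quoting); POSIXct columns are serialized as
#' zone-naive ISO-8601 seconds so that a write-then-read round trip is the
#' identity on the data model.
#'
#' @param x A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ehr_csv <- function(x, path) {
  x <- as_tibble(x)
  is_time <- vapply(x, inherits, logical(1), "POSIXct")
  x[is_time] <- lapply(x[is_time], format_clinic_time)
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
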