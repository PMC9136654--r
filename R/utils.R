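# Internal helpers shared across modules.

# Timestamps are a single zone-naive local clinic clock; they are stored as
# POSIXct in UTC purely as a container (no DST, no offsets).
EHR_TZ <- "UTC"
TS_FORMATS <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")

parse_clinic_time <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = EHR_TZ)
  todo <- !is.na(x) & nzchar(x)
  for (fmt in TS_FORMATS) {
    if (!any(todo)) break
    parsed <- as.POSIXct(x[todo], format = fmt, tz = EHR_TZ)
    ok <- !is.na(parsed)
    out[which(todo)[ok]] <- parsed[ok]
    todo[todo] <- !ok
  }
  out
}

format_clinic_time <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = EHR_TZ)
}

clinic_date <- function(x) {
  as.Date(x, tz = EHR_TZ)
}

# Cumulative sum restarting at each new value of a *contiguous* grouping
# vector. Used for laying out event trains without per-group loops.
grouped_cumsum <- function(x, g) {
  if (length(x) == 0L) return(numeric(0))
  cs <- cumsum(x)
  first <- !duplicated(g)
  offset <- (cs - x)[first][cumsum(first)]
  cs - offset
}

stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "ehrwow_input_error")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_input("%s is missing required column(s): %s", what,
               paste(missing, collapse = ", "))
  }
  invisible(df)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
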