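#' Parse a clock time to minutes since midnight
#'
#' Accepts `"H:MM"`, `"HH:MM"` or `"HH:MM:SS"` strings (seconds are kept as a
#' fraction of a minute).
#'
#' @param x character vector of clock times.
#' @return numeric vector of minutes since midnight.
#' @examples
#' parse_clock(c("8:40", "17:20"))
#' @export
parse_clock <- function(x) {
  stopifnot(is.character(x))
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (!length(p) %in% c(2L, 3L) || anyNA(suppressWarnings(as.numeric(p)))) {
      stop("invalid clock time: expected 'HH:MM' or 'HH:MM:SS'", call. = FALSE)
    }
    p <- as.numeric(p)
    if (p[1] > 24 || p[2] >= 60 || any(p < 0)) {
      stop("invalid clock time: hours in [0,24], minutes/seconds in [0,60)",
           call. = FALSE)
    }
    p[1] * 60 + p[2] + if (length(p) == 3L) p[3] / 60 else 0
  }, numeric(1))
}

#' Standard working-hours window
#'
#' The analysis window for within-work activity metrics. The default,
#' 8:40-17:20, is a 520-minute (8.67 h) standard workday; all working-hours
#' metrics are normalized onto this length (see
#' [normalize_to_working_hours()]).
#'
#' @param start,end clock-time strings; the window is half-open, `[start, end)`,
#'   and epoch membership is decided by the epoch's start timestamp.
#' @return an object of class `working_window` with elements `start_min`,
#'   `end_min`, `duration_min` and `duration_h` (hours, rounded to 2 decimals).
#' @examples
#' working_window()          # 520 min, 8.67 h
#' @export
working_window <- function(start = "8:40", end = "17:20") {
  s <- parse_clock(start)
  e <- parse_clock(end)
  if (e <= s) stop("working window end must be after start", call. = FALSE)
  structure(
    list(start_min = s, end_min = e,
         duration_min = e - s,
         duration_h = round((e - s) / 60, 2)),
    class = "working_window"
  )
}

#' @export
print.working_window <- function(x, ...) {
  cat(sprintf("working window %02d:%02d-%02d:%02d (%g min, %.2f h)\n",
              x$start_min %/% 60, round(x$start_min %% 60),
              x$end_min %/% 60, round(x$end_min %% 60),
              x$duration_min, x$duration_h))
  invisible(x)
}

# minute-of-day (possibly fractional) for POSIXct timestamps; all simulated
# timestamps are tz-naive and stored as UTC
minute_of_day <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  lt$hour * 60 + lt$min + lt$sec / 60
}
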