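#' Read and write the pipeline's CSV formats
#'
#' Epoch CSV: `participant_id, group, phase, timestamp, met`, timestamps
#' ISO 8601 at minute resolution, MET 0 = no signal. Entry/exit CSV:
#' `participant_id, group, phase, date, entry_time, exit_time` (repeated
#' rows per day allowed). Detection CSV: `day_index, timestamp, camera_id,
#' x_m, y_m` with `HH:MM:SS` timestamps.
#'
#' @param x table to write.
#' @param path file path.
#' @return writers return `path` invisibly; readers return a tibble.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_epoch_csv <- function(x, path) {
  out <- x
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_epoch_csv <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    group = readr::col_character(),
    phase = readr::col_character(),
    timestamp = readr::col_character(),
    met = readr::col_double()
  ))
  x$timestamp <- as.POSIXct(x$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                            tz = "UTC")
  if (anyNA(x$timestamp)) stop("unparseable timestamp in ", path, call. = FALSE)
  x
}

#' @rdname pipeline_io
#' @export
write_entry_exit_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_entry_exit_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    group = readr::col_character(),
    phase = readr::col_character(),
    date = readr::col_date(),
    entry_time = readr::col_character(),
    exit_time = readr::col_character()
  ))
}

#' @rdname pipeline_io
#' @export
write_detection_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_detection_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    day_index = readr::col_integer(),
    timestamp = readr::col_character(),
    camera_id = readr::col_character(),
    x_m = readr::col_double(),
    y_m = readr::col_double()
  ))
}
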