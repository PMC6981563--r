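#' Classify a 60-s epoch MET value into an intensity category
#'
#' Cut-points follow the standard worn-accelerometer convention: sedentary
#' behavior (SB) at <= 1.5 METs, light-intensity physical activity (LPA)
#' above 1.5 and below 3.0 METs, and moderate-to-vigorous activity (MVPA) at
#' >= 3.0 METs. A MET of exactly 0 is the no-signal sentinel emitted while
#' the device records nothing detectable; such epochs are non-wear
#' *candidates* and only become non-wear time when they form a long enough
#' run (see [detect_nonwear()]).
#'
#' @param met numeric vector of MET values, all `>= 0`.
#' @return factor with levels `nonwear_candidate`, `sb`, `lpa`, `mvpa`.
#' @examples
#' classify_epoch(c(0, 1.5, 1.6, 3.0))
#' @export
classify_epoch <- function(met) {
  if (anyNA(met)) stop("met values must not be NA", call. = FALSE)
  if (any(met < 0)) stop("met values must be >= 0", call. = FALSE)
  out <- character(length(met))
  out[met == 0] <- "nonwear_candidate"
  out[met > 0 & met <= 1.5] <- "sb"
  out[met > 1.5 & met < 3.0] <- "lpa"
  out[met >= 3.0] <- "mvpa"
  factor(out, levels = intensity_levels())
}

intensity_levels <- function() c("nonwear_candidate", "sb", "lpa", "mvpa")

#' Detect non-wear epochs
#'
#' Marks as non-wear every maximal run of at least `min_len` consecutive
#' no-signal epochs (MET = 0) within a calendar day; shorter zero-runs remain
#' wear time. Runs never span midnight because days are the analysis unit.
#'
#' @param epochs a data frame with columns `timestamp` (POSIXct, 60-s grid)
#'   and `met`; typically one participant-phase slice of an epoch table.
#' @param min_len minimum run length, in epochs (= minutes), default 20.
#' @return logical vector aligned to `epochs` rows: `TRUE` where the epoch is
#'   wear time, `FALSE` where it falls in a non-wear run.
#' @export
detect_nonwear <- function(epochs, min_len = 20) {
  stopifnot(is.data.frame(epochs), min_len >= 1)
  n <- nrow(epochs)
  if (n == 0L) return(logical(0))
  if (anyNA(epochs$met) || any(epochs$met < 0)) {
    stop("met values must be non-negative and non-missing", call. = FALSE)
  }
  day <- as.Date(epochs$timestamp, tz = "UTC")
  wear <- logical(n)
  for (idx in split(seq_len(n), day)) {
    z <- epochs$met[idx] == 0
    r <- rle(z)
    long_zero <- r$values & r$lengths >= min_len
    wear[idx] <- !inverse.rle(list(values = long_zero, lengths = r$lengths))
  }
  wear
}

#' Restrict an epoch table to the working-hours window
#'
#' Keeps exactly the epochs whose start timestamp falls in the half-open
#' window `[start, end)`.
#'
#' @param epochs data frame with a `timestamp` column.
#' @param window a [working_window()].
#' @return `epochs` filtered to the window.
#' @export
window_working_hours <- function(epochs, window = working_window()) {
  stopifnot(inherits(window, "working_window"))
  mod <- minute_of_day(epochs$timestamp)
  epochs[mod >= window$start_min & mod < window$end_min, , drop = FALSE]
}

#' Prolonged sedentary bouts in a category sequence
#'
#' Sums the maximal runs of consecutive SB epochs lasting at least `min_len`
#' minutes. Any non-SB epoch (LPA, MVPA or non-wear) breaks a run; no
#' interruption tolerance is applied.
#'
#' @param categories character or factor sequence of per-epoch categories for
#'   one contiguous day (or window) of epochs; only values equal to `"sb"`
#'   count towards a bout.
#' @param min_len minimum bout length in epochs (= minutes), default 30.
#' @return list with `prolonged_min` (total minutes in qualifying bouts) and
#'   `bouts`, a tibble of `start` index and `length` per qualifying bout.
#' @examples
#' detect_prolonged_sb(rep("sb", 30))$prolonged_min  # 30
#' detect_prolonged_sb(rep("sb", 29))$prolonged_min  # 0
#' @export
detect_prolonged_sb <- function(categories, min_len = 30) {
  x <- as.character(categories)
  if (length(x) == 0L) {
    return(list(prolonged_min = 0,
                bouts = tibble::tibble(start = integer(), length = integer())))
  }
  r <- rle(x == "sb")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  list(
    prolonged_min = sum(r$lengths[keep]),
    bouts = tibble::tibble(start = starts[keep], length = r$lengths[keep])
  )
}

# category counts for one contiguous, already-wear-masked epoch slice;
# wear-time zero epochs (zero-runs shorter than the non-wear cut-off) count
# as SB so that sb + lpa + mvpa partitions wear time exactly
wear_categories <- function(met, wear) {
  cat <- as.character(classify_epoch(met))
  cat[wear & cat == "nonwear_candidate"] <- "sb"
  cat[!wear] <- "nonwear"
  cat
}

summarize_one_window <- function(met, wear, prolonged_min_len) {
  cat <- wear_categories(met, wear)
  sb <- sum(cat == "sb")
  lpa <- sum(cat == "lpa")
  mvpa <- sum(cat == "mvpa")
  list(
    wear_min = sum(wear),
    sb_min = sb, lpa_min = lpa, mvpa_min = mvpa,
    total_pa_min = lpa + mvpa,
    prolonged_sb_min = detect_prolonged_sb(cat, prolonged_min_len)$prolonged_min
  )
}

#' Per-day activity summary
#'
#' Computes wear, SB, LPA, MVPA, total-PA and prolonged-SB minutes for the
#' whole day and for the working-hours window, flags weekend days, and marks
#' a day valid when all-day wear time reaches `valid_min` minutes (default
#' 600 = 10 h).
#'
#' @param epochs epoch table with columns `participant_id`, `group`, `phase`,
#'   `timestamp`, `met` (one or more participants/days).
#' @param window a [working_window()].
#' @param nonwear_min non-wear run cut-off in minutes (default 20).
#' @param prolonged_min prolonged-SB bout cut-off in minutes (default 30).
#' @param valid_min all-day wear minutes required for a valid day
#'   (default 600).
#' @return a tibble with one row per participant x phase x date carrying
#'   all-day (`*_allday`) and working-hours (`*_working`) metrics plus
#'   `weekend` and `valid_day` flags.
#' @export
summarize_day <- function(epochs, window = working_window(),
                          nonwear_min = 20, prolonged_min = 30,
                          valid_min = 600) {
  stopifnot(is.data.frame(epochs))
  need <- c("participant_id", "group", "phase", "timestamp", "met")
  if (!all(need %in% names(epochs))) {
    stop("epochs must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(epochs) == 0L) {
    return(tibble::tibble(
      participant_id = character(), group = character(), phase = character(),
      date = as.Date(character()), weekend = logical(),
      wear_min_allday = numeric(), sb_min_allday = numeric(),
      lpa_min_allday = numeric(), mvpa_min_allday = numeric(),
      total_pa_min_allday = numeric(), prolonged_sb_min_allday = numeric(),
      wear_min_working = numeric(), sb_min_working = numeric(),
      lpa_min_working = numeric(), mvpa_min_working = numeric(),
      total_pa_min_working = numeric(), prolonged_sb_min_working = numeric(),
      valid_day = logical()
    ))
  }
  epochs <- dplyr::arrange(epochs, .data$participant_id, .data$phase,
                           .data$timestamp)
  epochs$date <- as.Date(epochs$timestamp, tz = "UTC")
  out <- epochs |>
    dplyr::group_by(.data$participant_id, .data$group, .data$phase,
                    .data$date) |>
    dplyr::group_modify(function(d, key) {
      wear <- detect_nonwear(d, min_len = nonwear_min)
      all_day <- summarize_one_window(d$met, wear, prolonged_min)
      mod <- minute_of_day(d$timestamp)
      in_w <- mod >= window$start_min & mod < window$end_min
      wk <- summarize_one_window(d$met[in_w], wear[in_w], prolonged_min)
      tibble::tibble(
        weekend = format(key$date, "%u") %in% c("6", "7"),
        wear_min_allday = all_day$wear_min,
        sb_min_allday = all_day$sb_min,
        lpa_min_allday = all_day$lpa_min,
        mvpa_min_allday = all_day$mvpa_min,
        total_pa_min_allday = all_day$total_pa_min,
        prolonged_sb_min_allday = all_day$prolonged_sb_min,
        wear_min_working = wk$wear_min,
        sb_min_working = wk$sb_min,
        lpa_min_working = wk$lpa_min,
        mvpa_min_working = wk$mvpa_min,
        total_pa_min_working = wk$total_pa_min,
        prolonged_sb_min_working = wk$prolonged_sb_min,
        valid_day = all_day$wear_min >= valid_min
      )
    }) |>
    dplyr::ungroup()
  out
}

#' Rescale an observed duration onto the standard working-hours length
#'
#' `observed / wearing * duration_min`, the min/working-hours unit: what the
#' observed duration would be had the device been worn for the full standard
#' workday (520 min by default).
#'
#' @param observed_min observed duration in minutes (vectorized).
#' @param wearing_min wearing time over the same window, minutes; must be
#'   positive.
#' @param window a [working_window()].
#' @return normalized minutes per working-hours.
#' @examples
#' normalize_to_working_hours(250, 500)  # 260
#' @export
normalize_to_working_hours <- function(observed_min, wearing_min,
                                       window = working_window()) {
  if (any(wearing_min <= 0)) {
    stop("wearing_min must be positive (day should already be invalid)",
         call. = FALSE)
  }
  if (any(observed_min < 0) || any(observed_min > wearing_min)) {
    stop("observed_min must lie in [0, wearing_min]", call. = FALSE)
  }
  observed_min / wearing_min * window$duration_min
}

#' Retain participants with enough valid measurement days
#'
#' A participant-phase is retained when it has at least `min_valid_days`
#' valid weekdays; under the default `"per-week"` rule the requirement must
#' hold in every Monday-Friday working week the participant's weekday data
#' touch, under `"overall"` it is applied to the phase total.
#'
#' @param days a [summarize_day()] table.
#' @param min_valid_days required valid weekdays (default 4).
#' @param week_rule `"per-week"` or `"overall"`.
#' @return tibble of `participant_id`, `phase`, `retained`.
#' @export
filter_valid_participants <- function(days, min_valid_days = 4,
                                      week_rule = c("per-week", "overall")) {
  week_rule <- match.arg(week_rule)
  wd <- days[!days$weekend, , drop = FALSE]
  if (nrow(wd) == 0L) {
    return(tibble::tibble(participant_id = character(), phase = character(),
                          retained = logical()))
  }
  # ISO week id: the Monday of the week containing the date
  wd$week <- wd$date - (as.integer(format(wd$date, "%u")) - 1L)
  if (week_rule == "per-week") {
    wd |>
      dplyr::group_by(.data$participant_id, .data$phase, .data$week) |>
      dplyr::summarise(n_valid = sum(.data$valid_day), .groups = "drop") |>
      dplyr::group_by(.data$participant_id, .data$phase) |>
      dplyr::summarise(retained = all(.data$n_valid >= min_valid_days),
                       .groups = "drop")
  } else {
    wd |>
      dplyr::group_by(.data$participant_id, .data$phase) |>
      dplyr::summarise(retained = sum(.data$valid_day) >= min_valid_days,
                       .groups = "drop")
  }
}

#' Average daily in-office hours from an entry/exit log
#'
#' @param entry_exit tibble with `participant_id`, `phase`, `date`,
#'   `entry_time`, `exit_time` (clock strings; several rows per day allowed).
#' @return tibble `participant_id`, `phase`, `time_in_office_h` (mean of the
#'   daily summed exit-entry intervals).
#' @export
time_in_office <- function(entry_exit) {
  ent <- parse_clock(entry_exit$entry_time)
  ext <- parse_clock(entry_exit$exit_time)
  if (any(ext <= ent)) stop("exit_time must be after entry_time", call. = FALSE)
  entry_exit$hours <- (ext - ent) / 60
  entry_exit |>
    dplyr::group_by(.data$participant_id, .data$phase, .data$date) |>
    dplyr::summarise(hours = sum(.data$hours), .groups = "drop") |>
    dplyr::group_by(.data$participant_id, .data$phase) |>
    dplyr::summarise(time_in_office_h = mean(.data$hours), .groups = "drop")
}

#' Per-phase activity summary across valid weekdays
#'
#' Averages day summaries over each participant's valid weekdays in a phase.
#' Working-hours metrics are normalized to min/working-hours *per day* and
#' then averaged (so SB + total PA = 520 exactly for every participant);
#' all-day metrics are reported raw, so SB + total PA equals all-day wear
#' time.
#'
#' @param days a [summarize_day()] table.
#' @param entry_exit optional entry/exit log (see [time_in_office()]).
#' @param window a [working_window()].
#' @param min_valid_days,week_rule passed to [filter_valid_participants()].
#' @return one row per retained participant x phase: `n_valid_days`, raw
#'   all-day and working means, normalized working-hours metrics (`*_norm`)
#'   and, when a log is supplied, `time_in_office_h`.
#' @export
summarize_phase <- function(days, entry_exit = NULL,
                            window = working_window(),
                            min_valid_days = 4,
                            week_rule = c("per-week", "overall")) {
  week_rule <- match.arg(week_rule)
  keep <- filter_valid_participants(days, min_valid_days, week_rule)
  keep <- keep[keep$retained, c("participant_id", "phase")]
  use <- dplyr::inner_join(days, keep, by = c("participant_id", "phase"))
  use <- use[!use$weekend & use$valid_day, , drop = FALSE]
  if (nrow(use) == 0L) stop("no valid days left after filtering", call. = FALSE)
  if (any(use$wear_min_working <= 0)) {
    stop("valid day with zero working-hours wear time; cannot normalize",
         call. = FALSE)
  }
  norm <- function(obs, wear) normalize_to_working_hours(obs, wear, window)
  out <- use |>
    dplyr::mutate(
      sb_norm = norm(.data$sb_min_working, .data$wear_min_working),
      lpa_norm = norm(.data$lpa_min_working, .data$wear_min_working),
      mvpa_norm = norm(.data$mvpa_min_working, .data$wear_min_working),
      total_pa_norm = norm(.data$total_pa_min_working, .data$wear_min_working),
      prolonged_sb_norm = norm(.data$prolonged_sb_min_working,
                               .data$wear_min_working)
    ) |>
    dplyr::group_by(.data$participant_id, .data$group, .data$phase) |>
    dplyr::summarise(
      n_valid_days = dplyr::n(),
      dplyr::across(c(dplyr::ends_with("_allday"), dplyr::ends_with("_working"),
                      dplyr::ends_with("_norm")), mean),
      .groups = "drop"
    )
  if (!is.null(entry_exit)) {
    tio <- time_in_office(entry_exit)
    out <- dplyr::left_join(out, tio, by = c("participant_id", "phase"))
  }
  out
}
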