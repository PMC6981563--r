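#' Assign floor coordinates to office zones
#'
#' Point-in-polygon assignment of detection coordinates to the plan's
#' labelled zones. Containment includes polygon boundaries; where zones
#' overlap, the highest `priority` wins and remaining ties break
#' lexicographically by label. Points inside no zone get `NA`.
#'
#' @param x,y numeric coordinate vectors (floor meters).
#' @param plan an [office_plan()].
#' @return character vector of zone labels (or `NA`).
#' @export
assign_zone <- function(x, y, plan) {
  stopifnot(length(x) == length(y), nrow(plan) > 0)
  ord <- order(-plan$priority, plan$label)
  out <- rep(NA_character_, length(x))
  for (i in ord) {
    todo <- is.na(out)
    if (!any(todo)) break
    inside <- pracma::inpolygon(x[todo], y[todo],
                                plan$polygon[[i]][, 1], plan$polygon[[i]][, 2],
                                boundary = TRUE)
    out[which(todo)[inside]] <- plan$label[i]
  }
  out
}

#' Aggregate a detection log into per-zone 15-minute slot counts
#'
#' Assigns each detection to a zone, bins its timestamp into half-open
#' `slot_len`-minute slots over `[start, end)`, and tallies counts per
#' zone x day x slot. Every zone appears in every day/slot cell, with count
#' 0 where nothing was detected. Detections outside the window or inside no
#' zone are dropped; their counts are recorded in the `dropped` attribute
#' and reported via a message.
#'
#' @param log detection tibble with `day_index`, `timestamp` (`"HH:MM:SS"`),
#'   `x_m`, `y_m`.
#' @param plan an [office_plan()].
#' @param start,end recording window clock times (defaults 10:00 / 17:00).
#' @param slot_len slot length in minutes (default 15); must divide the
#'   window evenly.
#' @return tibble `label`, `category`, `day_index`, `slot_index`, `count`
#'   with attribute `dropped = c(out_of_window = , unassigned = )`.
#' @export
aggregate_slot_counts <- function(log, plan, start = "10:00", end = "17:00",
                                  slot_len = 15) {
  s <- parse_clock(start); e <- parse_clock(end)
  if (e <= s) stop("end must be after start", call. = FALSE)
  n_slots <- (e - s) / slot_len
  if (abs(n_slots - round(n_slots)) > 1e-9) {
    stop("window length must be divisible by slot_len", call. = FALSE)
  }
  n_slots <- as.integer(round(n_slots))
  days <- if (nrow(log)) sort(unique(log$day_index)) else integer(0)

  tod <- if (nrow(log)) parse_clock(log$timestamp) else numeric(0)
  in_window <- tod >= s & tod < e
  n_out <- sum(!in_window)
  log <- log[in_window, , drop = FALSE]
  tod <- tod[in_window]

  lab <- assign_zone(log$x_m, log$y_m, plan)
  n_unassigned <- sum(is.na(lab))
  keep <- !is.na(lab)

  tallied <- tibble::tibble(
    label = lab[keep],
    day_index = log$day_index[keep],
    slot_index = as.integer(floor((tod[keep] - s) / slot_len))
  ) |>
    dplyr::count(.data$label, .data$day_index, .data$slot_index,
                 name = "count")

  grid <- tidyr::expand_grid(
    label = plan$label,
    day_index = if (length(days)) days else 1L,
    slot_index = seq_len(n_slots) - 1L
  )
  out <- grid |>
    dplyr::left_join(tallied, by = c("label", "day_index", "slot_index")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::left_join(plan[, c("label", "category")], by = "label") |>
    dplyr::select("label", "category", "day_index", "slot_index", "count") |>
    dplyr::arrange(.data$label, .data$day_index, .data$slot_index)
  if (n_out + n_unassigned > 0) {
    message(sprintf("dropped %d detection(s): %d outside [%s, %s), %d in no zone",
                    n_out + n_unassigned, n_out, start, end, n_unassigned))
  }
  attr(out, "dropped") <- c(out_of_window = n_out, unassigned = n_unassigned)
  out
}

#' Summarize space utilization per zone or category
#'
#' Mean and dispersion of the detectable number of persons per 15-min slot
#' for each space, over the space's day x slot cells (the default), over day
#' totals, or over slot means.
#'
#' @param slot_counts an [aggregate_slot_counts()] table.
#' @param level `"zone"` (per label) or `"category"` (counts of a category's
#'   zones summed per cell first).
#' @param se_over cells over which the standard error is computed:
#'   `"cells"` (day x slot), `"days"` or `"slots"`.
#' @return tibble `space`, `category`, `mean_per_slot`, `se`, `n_cells`,
#'   ordered aisles before workstations as in standard utilization tables.
#' @export
summarize_space <- function(slot_counts, level = c("zone", "category"),
                            se_over = c("cells", "days", "slots")) {
  level <- match.arg(level)
  se_over <- match.arg(se_over)
  if (nrow(slot_counts) == 0L) stop("no slot counts to summarize", call. = FALSE)
  key <- if (level == "zone") "label" else "category"
  cells <- slot_counts |>
    dplyr::group_by(.data[[key]], .data$category, .data$day_index,
                    .data$slot_index) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  grouped <- switch(
    se_over,
    cells = cells,
    days = cells |>
      dplyr::group_by(.data[[key]], .data$category, .data$day_index) |>
      dplyr::summarise(count = mean(.data$count), .groups = "drop"),
    slots = cells |>
      dplyr::group_by(.data[[key]], .data$category, .data$slot_index) |>
      dplyr::summarise(count = mean(.data$count), .groups = "drop")
  )
  aisle_first <- c("main_aisle", "multiple_usage_aisle",
                   "around_workstation_aisle", "dedicated_workstation",
                   "shared_workstation")
  out <- grouped |>
    dplyr::group_by(space = .data[[key]], category = .data$category) |>
    dplyr::summarise(
      mean_per_slot = mean(.data$count),
      se = stats::sd(.data$count) / sqrt(dplyr::n()),
      n_cells = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$category, aisle_first), .data$space)
  if (level == "category") out$space <- out$category
  out
}

#' Per-slot occupancy profiles
#'
#' Builds the per-zone slot time series used for shared-workstation
#' utilization figures: one series per recording day plus the across-day
#' mean.
#'
#' @param slot_counts an [aggregate_slot_counts()] table.
#' @param zones zone labels to profile; defaults to all shared workstations
#'   present, else all zones.
#' @return tibble `label`, `series` (`"day <i>"` or `"mean"`), `slot_index`,
#'   `count`.
#' @export
slot_profile <- function(slot_counts, zones = NULL) {
  if (is.null(zones)) {
    shared <- unique(slot_counts$label[slot_counts$category ==
                                         "shared_workstation"])
    zones <- if (length(shared)) shared else unique(slot_counts$label)
  }
  missing_z <- setdiff(zones, unique(slot_counts$label))
  if (length(missing_z)) {
    stop("unknown zone(s): ", paste(missing_z, collapse = ", "), call. = FALSE)
  }
  sub <- slot_counts[slot_counts$label %in% zones, , drop = FALSE]
  daily <- sub |>
    dplyr::transmute(label = .data$label,
                     series = sprintf("day %d", .data$day_index),
                     slot_index = .data$slot_index, count = .data$count)
  means <- sub |>
    dplyr::group_by(.data$label, .data$slot_index) |>
    dplyr::summarise(count = mean(.data$count), .groups = "drop") |>
    dplyr::mutate(series = "mean") |>
    dplyr::select("label", "series", "slot_index", "count")
  dplyr::bind_rows(daily, means) |>
    dplyr::arrange(.data$label, .data$series, .data$slot_index)
}
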