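#' Configuration for the synthetic person-detection log
#'
#' Fixed-camera person detections are emulated as per-zone Poisson counts in
#' each 15-minute slot of a 10:00-17:00 recording day, with detection
#' coordinates placed uniformly inside the source zone's polygon.
#'
#' @param zone_intensities named numeric: mean detections per slot for each
#'   zone label; zones not named receive 0.
#' @param n_days recording days (default 3).
#' @param slot_len slot length in minutes (default 15).
#' @param record_start,record_end recording window clock times
#'   (defaults 10:00 / 17:00, i.e. 28 slots of 15 min).
#' @param seed integer seed; mandatory.
#' @return a validated list of class `video_sim_config`.
#' @export
video_sim_config <- function(zone_intensities, n_days = 3, slot_len = 15,
                             record_start = "10:00", record_end = "17:00",
                             seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(names(zone_intensities)) || any(names(zone_intensities) == "")) {
    stop("zone_intensities must be a named numeric vector", call. = FALSE)
  }
  if (any(zone_intensities < 0)) {
    stop("zone intensities must be >= 0", call. = FALSE)
  }
  s <- parse_clock(record_start); e <- parse_clock(record_end)
  if (e <= s) stop("record_end must be after record_start", call. = FALSE)
  structure(
    list(zone_intensities = zone_intensities, n_days = as.integer(n_days),
         slot_len = slot_len, record_start = record_start,
         record_end = record_end, seed = as.integer(seed)),
    class = "video_sim_config"
  )
}

#' Per-zone default detection intensities
#'
#' Magnitude-realistic mean detections per 15-min slot by zone category:
#' dedicated workstation banks dominate (order 1000 detections/slot), shared
#' workstations and aisles are an order of magnitude lower.
#'
#' @param plan an [office_plan()].
#' @return named numeric vector over the plan's zone labels.
#' @export
default_zone_intensities <- function(plan) {
  base <- c(main_aisle = 60, around_workstation_aisle = 64,
            multiple_usage_aisle = 80, dedicated_workstation = 1000,
            shared_workstation = 240)
  out <- base[plan$category]
  # shared workstations split the category total between them
  shared <- plan$category == "shared_workstation"
  if (sum(shared) > 1) out[shared] <- base[["shared_workstation"]] / sum(shared)
  names(out) <- plan$label
  out
}

# uniform points strictly inside a polygon, by bbox rejection sampling
sample_points_in_polygon <- function(n, poly) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16L)
    x <- stats::runif(m, xr[1], xr[2])
    y <- stats::runif(m, yr[1], yr[2])
    keep <- pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = FALSE)
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Simulate a person-detection log over an office plan
#'
#' For each zone, day and 15-min slot, draws a Poisson count with the zone's
#' configured intensity and emits that many detection records with uniform
#' timestamps in the slot and coordinates strictly inside the zone polygon.
#'
#' @param plan an [office_plan()].
#' @param config a [video_sim_config()]; its intensity names must be a subset
#'   of the plan's zone labels.
#' @return tibble `day_index`, `timestamp` (`"HH:MM:SS"` clock string),
#'   `camera_id`, `x_m`, `y_m`.
#' @export
simulate_detections <- function(plan, config) {
  stopifnot(inherits(config, "video_sim_config"))
  unknown <- setdiff(names(config$zone_intensities), plan$label)
  if (length(unknown)) {
    stop("unknown zone label(s) in intensities: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  s <- parse_clock(config$record_start)
  e <- parse_clock(config$record_end)
  n_slots <- as.integer((e - s) / config$slot_len)
  fmt <- function(min_of_day) {
    sec <- round(min_of_day * 60)
    sprintf("%02d:%02d:%02d", sec %/% 3600, (sec %% 3600) %/% 60, sec %% 60)
  }
  rows <- list()
  withr::with_seed(config$seed, {
    for (zi in seq_len(nrow(plan))) {
      lab <- plan$label[zi]
      lambda <- config$zone_intensities[lab]
      if (is.na(lambda) || lambda == 0) next
      cam <- sprintf("cam%02d", zi)
      for (day in seq_len(config$n_days)) {
        counts <- stats::rpois(n_slots, lambda)
        total <- sum(counts)
        if (total == 0L) next
        pts <- sample_points_in_polygon(total, plan$polygon[[zi]])
        slot_of <- rep(seq_len(n_slots) - 1L, counts)
        tod <- s + (slot_of + stats::runif(total)) * config$slot_len
        # keep strictly inside the half-open slot after rounding to seconds
        tod <- pmin(tod, s + (slot_of + 1L) * config$slot_len - 1 / 60)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          day_index = day, timestamp = fmt(tod), camera_id = cam,
          x_m = pts[, 1], y_m = pts[, 2]
        )
      }
    }
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(day_index = integer(), timestamp = character(),
                          camera_id = character(), x_m = numeric(),
                          y_m = numeric())
  }
  dplyr::arrange(out, .data$day_index, .data$timestamp, .data$camera_id)
}
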