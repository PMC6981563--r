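# Independent brute-force oracles. Deliberately written with plain index
# loops (no rle, no inpolygon) so they share no code path with the package.

# indices of epochs inside maximal zero-MET runs of length >= min_len
oracle_nonwear_mask <- function(met, min_len) {
  n <- length(met)
  wear <- rep(TRUE, n)
  i <- 1
  while (i <= n) {
    if (met[i] == 0) {
      j <- i
      while (j < n && met[j + 1] == 0) j <- j + 1
      if (j - i + 1 >= min_len) wear[i:j] <- FALSE
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  wear
}

# total minutes inside maximal SB runs of length >= min_len
oracle_prolonged_min <- function(categories, min_len) {
  x <- as.character(categories)
  n <- length(x)
  total <- 0L
  i <- 1
  while (i <= n) {
    if (x[i] == "sb") {
      j <- i
      while (j < n && x[j + 1] == "sb") j <- j + 1
      if (j - i + 1 >= min_len) total <- total + (j - i + 1L)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  total
}

# even-odd ray casting, counting boundary points as inside
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly) - 1  # closed ring: last vertex repeats the first
  inside <- FALSE
  for (k in seq_len(n)) {
    x1 <- poly[k, 1]; y1 <- poly[k, 2]
    x2 <- poly[k + 1, 1]; y2 <- poly[k + 1, 2]
    # on-edge check via collinearity + bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(cross) < 1e-12 &&
        px >= min(x1, x2) - 1e-12 && px <= max(x1, x2) + 1e-12 &&
        py >= min(y1, y2) - 1e-12 && py <= max(y1, y2) + 1e-12) {
      return(TRUE)
    }
    if ((y1 > py) != (y2 > py)) {
      x_int <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < x_int) inside <- !inside
    }
  }
  inside
}

oracle_assign_zone <- function(px, py, plan) {
  ord <- order(-plan$priority, plan$label)
  for (i in ord) {
    if (oracle_point_in_polygon(px, py, plan$polygon[[i]])) {
      return(plan$label[i])
    }
  }
  NA_character_
}

# random epoch table for one synthetic participant-day
random_epoch_day <- function(n, p_zero = 0.3, date = as.Date("2023-05-01")) {
  met <- ifelse(stats::runif(n) < p_zero, 0, stats::runif(n, 0.5, 5))
  tibble::tibble(
    timestamp = as.POSIXct(paste(date, "07:00:00"), tz = "UTC") +
      (seq_len(n) - 1) * 60,
    met = met
  )
}

# small cohort config for fast tests
small_config <- function(seed, ...) {
  accel_sim_config(n_per_group = c(control = 4, renovation = 3),
                   n_weekdays = 5, seed = seed, ...)
}
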