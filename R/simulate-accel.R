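#' Configuration for the synthetic accelerometer cohort
#'
#' Defines the study conditions the generator emulates: a two-arm office
#' cohort wearing a 60-s-epoch MET accelerometer over two working weeks per
#' phase, with a renovation-arm post-phase shift of sedentary minutes into
#' light activity. The working-hours cell means are expressed in
#' min/working-hours (the 520-min standard-workday scale); by default they
#' are the renovation-arm baseline composition SB 346.8 / LPA 130.4 /
#' MVPA 42.8, which sums to exactly 520 so the normalization pipeline
#' recovers the configured means regardless of wear gaps.
#'
#' @param n_per_group named counts per arm, e.g.
#'   `c(control = 29, renovation = 13)`.
#' @param n_weekdays measurement weekdays per phase (default 10 = two working
#'   weeks).
#' @param epoch_len epoch length in seconds; fixed at 60.
#' @param wear_start,wear_end waking wear window clock times.
#' @param nonwear_gap_rate expected number of device-off gaps per day
#'   (Poisson).
#' @param nonwear_gap_len gap length in minutes (>= the non-wear cut-off of
#'   20 so gaps register as non-wear).
#' @param working_sb_min,working_lpa_min,working_mvpa_min mean minutes per
#'   working-hours window per category; their sum must not exceed the window
#'   length.
#' @param sd_between between-participant SD of SB minutes (a stable random
#'   intercept shared by both phases, traded against LPA).
#' @param sd_within day-to-day SD of SB minutes (likewise traded against
#'   LPA).
#' @param effect_sb_change minutes moved from SB to LPA in the renovation
#'   arm's post phase (default 25, a typical activity-based-working office
#'   renovation effect per 8.67-h workday).
#' @param bout_persistence self-transition weight of the per-epoch intensity
#'   Markov chain in `[0, 1)`; higher values give longer sedentary bouts.
#' @param seed integer seed; mandatory.
#' @return a validated list of class `accel_sim_config`.
#' @export
accel_sim_config <- function(n_per_group = c(control = 29, renovation = 13),
                             n_weekdays = 10,
                             epoch_len = 60,
                             wear_start = "7:00", wear_end = "22:00",
                             nonwear_gap_rate = 1, nonwear_gap_len = 25,
                             working_sb_min = 346.8,
                             working_lpa_min = 130.4,
                             working_mvpa_min = 42.8,
                             sd_between = 26, sd_within = 25,
                             effect_sb_change = 25,
                             bout_persistence = 0.85,
                             seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (epoch_len != 60) stop("epoch_len is fixed at 60 s", call. = FALSE)
  if (!all(c("control", "renovation") %in% names(n_per_group))) {
    stop("n_per_group must name 'control' and 'renovation' arms",
         call. = FALSE)
  }
  means <- c(working_sb_min, working_lpa_min, working_mvpa_min)
  if (any(means < 0) || nonwear_gap_rate < 0 || nonwear_gap_len < 0 ||
      sd_between < 0 || sd_within < 0) {
    stop("durations, rates and SDs must be non-negative", call. = FALSE)
  }
  win <- working_window()
  if (sum(means) > win$duration_min + 1e-9) {
    stop(sprintf(
      "configured category means sum to %.1f min, exceeding the %g-min window",
      sum(means), win$duration_min), call. = FALSE)
  }
  if (bout_persistence < 0 || bout_persistence >= 1) {
    stop("bout_persistence must be in [0, 1)", call. = FALSE)
  }
  if (parse_clock(wear_end) <= parse_clock(wear_start)) {
    stop("wear_end must be after wear_start", call. = FALSE)
  }
  structure(
    list(n_per_group = n_per_group, n_weekdays = n_weekdays,
         epoch_len = epoch_len,
         wear_start = wear_start, wear_end = wear_end,
         nonwear_gap_rate = nonwear_gap_rate,
         nonwear_gap_len = nonwear_gap_len,
         working_sb_min = working_sb_min,
         working_lpa_min = working_lpa_min,
         working_mvpa_min = working_mvpa_min,
         sd_between = sd_between, sd_within = sd_within,
         effect_sb_change = effect_sb_change,
         bout_persistence = bout_persistence,
         seed = as.integer(seed)),
    class = "accel_sim_config"
  )
}

# first measurement Monday of each phase
phase_anchor <- function(phase) {
  switch(phase, pre = as.Date("2017-11-06"), post = as.Date("2018-07-23"))
}

# n consecutive weekdays starting at a Monday
weekday_dates <- function(anchor, n) {
  d <- anchor + 0:(ceiling(n / 5) * 7 + 6)
  d <- d[!format(d, "%u") %in% c("6", "7")]
  d[seq_len(n)]
}

# sticky Markov chain with stationary distribution p: at each epoch the chain
# renews with prob (1 - rho) and redraws from p, otherwise keeps its state;
# vectorized via renewal-block fill-forward
sample_sticky_chain <- function(n, p, rho) {
  renew <- c(TRUE, stats::runif(n - 1) < (1 - rho))
  block <- cumsum(renew)
  draws <- sample.int(length(p), max(block), replace = TRUE, prob = p)
  draws[block]
}

met_for_state <- function(state) {
  n <- length(state)
  met <- numeric(n)
  met[state == 1L] <- stats::runif(sum(state == 1L), 1.0, 1.5)
  met[state == 2L] <- stats::runif(sum(state == 2L), 1.6, 2.9)
  met[state == 3L] <- stats::runif(sum(state == 3L), 3.0, 6.0)
  met
}

#' Simulate epoch MET series for one group x phase cell
#'
#' One series per simulated participant: 60-s epochs over the waking wear
#' window on each measurement weekday. Per-epoch intensity states are drawn
#' from a sticky three-state Markov chain whose stationary distribution
#' matches the day's target SB/LPA/MVPA composition, so sedentary bouts have
#' realistic run structure; device-off gaps are inserted as contiguous
#' MET = 0 (no-signal) runs. Participant-level SB deviations are a random
#' intercept shared across phases (the cohort is a repeated-measures design),
#' traded minute-for-minute against LPA; the renovation arm's post phase
#' additionally moves `effect_sb_change` minutes from SB to LPA.
#'
#' @param config an [accel_sim_config()].
#' @param group `"control"` or `"renovation"`.
#' @param phase `"pre"` or `"post"`.
#' @return tibble of epochs: `participant_id`, `group`, `phase`, `timestamp`
#'   (POSIXct UTC), `met`.
#' @export
simulate_epoch_series <- function(config, group = c("control", "renovation"),
                                  phase = c("pre", "post")) {
  stopifnot(inherits(config, "accel_sim_config"))
  group <- match.arg(group)
  phase <- match.arg(phase)
  n <- config$n_per_group[[group]]
  ids <- sprintf("%s_%02d", group, seq_len(n))

  # stable participant intercepts: same seed for both phases of a group
  b <- withr::with_seed(
    (config$seed + 97L * match(group, c("control", "renovation"))) %% .Machine$integer.max,
    stats::rnorm(n, 0, config$sd_between)
  )

  shift <- if (group == "renovation" && phase == "post") {
    config$effect_sb_change
  } else 0

  wear_s <- parse_clock(config$wear_start)
  wear_e <- parse_clock(config$wear_end)
  n_epoch <- as.integer(wear_e - wear_s)
  dates <- weekday_dates(phase_anchor(phase), config$n_weekdays)
  targets <- c(config$working_sb_min, config$working_lpa_min,
               config$working_mvpa_min)

  phase_seed <- (config$seed + 1009L * match(phase, c("pre", "post")) +
                   9973L * match(group, c("control", "renovation"))) %%
    .Machine$integer.max

  withr::with_seed(phase_seed, {
    per_participant <- lapply(seq_len(n), function(i) {
      per_day <- lapply(seq_along(dates), function(d) {
        eps <- stats::rnorm(1, 0, config$sd_within)
        sb <- max(targets[1] + b[i] + eps - shift, 0)
        lpa <- max(targets[2] - b[i] - eps + shift, 0)
        p <- c(sb, lpa, targets[3])
        p <- p / sum(p)
        state <- sample_sticky_chain(n_epoch, p, config$bout_persistence)
        met <- met_for_state(state)
        # device-off gaps: contiguous zero runs of fixed length
        n_gaps <- stats::rpois(1, config$nonwear_gap_rate)
        gap_len <- as.integer(config$nonwear_gap_len)
        if (n_gaps > 0 && gap_len > 0 && gap_len < n_epoch) {
          for (s in sample.int(n_epoch - gap_len + 1L, n_gaps, replace = TRUE)) {
            met[s:(s + gap_len - 1L)] <- 0
          }
        }
        ts0 <- as.POSIXct(paste(dates[d], "00:00:00"), tz = "UTC") +
          wear_s * 60
        tibble::tibble(timestamp = ts0 + (seq_len(n_epoch) - 1L) * 60,
                       met = met)
      })
      out <- dplyr::bind_rows(per_day)
      out$participant_id <- ids[i]
      out
    })
    res <- dplyr::bind_rows(per_participant)
  })
  res$group <- group
  res$phase <- phase
  res[, c("participant_id", "group", "phase", "timestamp", "met")]
}

#' Simulate the full two-arm, two-phase epoch cohort
#'
#' @param config an [accel_sim_config()].
#' @return epoch tibble binding all four group x phase cells.
#' @export
simulate_cohort <- function(config) {
  dplyr::bind_rows(lapply(c("control", "renovation"), function(g) {
    dplyr::bind_rows(lapply(c("pre", "post"), function(p) {
      simulate_epoch_series(config, g, p)
    }))
  }))
}

#' Simulate office entry/exit logs
#'
#' Per participant per measurement weekday, one or (occasionally) two
#' entry/exit pairs whose daily total hours vary around `mean_hours`.
#'
#' @param config an [accel_sim_config()].
#' @param mean_hours mean daily in-office hours, in (0, 24].
#' @param sd_hours day-to-day SD of the daily total (default 1).
#' @return tibble `participant_id`, `group`, `phase`, `date`, `entry_time`,
#'   `exit_time`.
#' @export
simulate_entry_exit <- function(config, mean_hours = 7, sd_hours = 1) {
  stopifnot(inherits(config, "accel_sim_config"))
  if (mean_hours <= 0 || mean_hours > 24) {
    stop("mean_hours must be in (0, 24]", call. = FALSE)
  }
  fmt <- function(min_of_day) {
    sprintf("%02d:%02d:%02d", floor(min_of_day / 60) %% 24,
            floor(min_of_day) %% 60, round((min_of_day %% 1) * 60))
  }
  rows <- list()
  withr::with_seed((config$seed + 777L) %% .Machine$integer.max, {
    for (g in c("control", "renovation")) {
      n <- config$n_per_group[[g]]
      for (p in c("pre", "post")) {
        dates <- weekday_dates(phase_anchor(p), config$n_weekdays)
        for (i in seq_len(n)) {
          id <- sprintf("%s_%02d", g, i)
          for (d in dates) {
            tot <- min(max(stats::rnorm(1, mean_hours, sd_hours), 0.5), 13) * 60
            entry <- parse_clock("8:40") + stats::rnorm(1, 0, 15)
            if (stats::runif(1) < 0.25 && tot > 120) {
              # split day: an out-of-office break in the middle
              first <- stats::runif(1, 0.3, 0.7) * tot
              brk <- stats::runif(1, 30, 90)
              rows[[length(rows) + 1L]] <- tibble::tibble(
                participant_id = id, group = g, phase = p,
                date = as.Date(d, origin = "1970-01-01"),
                entry_time = c(fmt(entry), fmt(entry + first + brk)),
                exit_time = c(fmt(entry + first),
                              fmt(entry + brk + tot))
              )
            } else {
              rows[[length(rows) + 1L]] <- tibble::tibble(
                participant_id = id, group = g, phase = p,
                date = as.Date(d, origin = "1970-01-01"),
                entry_time = fmt(entry), exit_time = fmt(entry + tot)
              )
            }
          }
        }
      }
    }
  })
  dplyr::bind_rows(rows)
}
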