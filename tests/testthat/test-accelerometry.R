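test_that("MET cut-points classify the documented boundaries", {
  expect_equal(as.character(classify_epoch(c(0, 1.5, 1.6, 3.0, 1.55, 0.1))),
               c("nonwear_candidate", "sb", "lpa", "mvpa", "lpa", "sb"))
  expect_error(classify_epoch(-0.1), "met values must be >= 0")
  expect_error(classify_epoch(NA_real_), "NA")
})

test_that("category partition: every epoch gets exactly one category", {
  set.seed(11)
  met <- c(0, runif(500, 0, 6))
  cat <- classify_epoch(met)
  expect_false(anyNA(cat))
  expect_equal(sum(table(cat)), length(met))
})

test_that("non-wear marks 20-min zero runs but not 19-min runs", {
  day <- random_epoch_day(100, p_zero = 0)
  day$met[30:49] <- 0  # 20 consecutive zero epochs
  expect_equal(which(!detect_nonwear(day)), 30:49)
  day$met[30] <- 1  # now only 19
  expect_true(all(detect_nonwear(day)))
  expect_length(detect_nonwear(day[0, ]), 0)
})

test_that("non-wear runs do not span midnight", {
  d1 <- random_epoch_day(30, p_zero = 0, date = as.Date("2023-05-01"))
  d2 <- random_epoch_day(30, p_zero = 0, date = as.Date("2023-05-02"))
  d1$timestamp <- as.POSIXct("2023-05-01 23:30:00", tz = "UTC") + (0:29) * 60
  d2$timestamp <- as.POSIXct("2023-05-02 00:00:00", tz = "UTC") + (0:29) * 60
  both <- rbind(d1, d2)
  # 15 zero min before midnight + 30 zero min after: a 45-min zero run if
  # runs crossed midnight, but only the day-2 segment qualifies
  both$met[16:60] <- 0
  wear <- detect_nonwear(both, min_len = 20)
  expect_true(all(wear[1:30]))
  expect_true(all(!wear[31:60]))
})

test_that("non-wear detection matches the brute-force run oracle", {
  set.seed(21)
  for (i in 1:200) {
    day <- random_epoch_day(sample(50:500, 1), p_zero = runif(1, 0.05, 0.6))
    expect_identical(detect_nonwear(day), oracle_nonwear_mask(day$met, 20))
  }
})

test_that("the standard working window is 520 min / 8.67 h and half-open", {
  w <- working_window()
  expect_identical(w$duration_min, 520)
  expect_identical(w$duration_h, 8.67)

  ts <- as.POSIXct("2023-05-01 00:00:00", tz = "UTC") +
    c(8 * 3600 + 39 * 60, 8 * 3600 + 40 * 60, 12 * 3600,
      17 * 3600 + 19 * 60, 17 * 3600 + 20 * 60)
  d <- tibble::tibble(timestamp = ts, met = 1)
  kept <- window_working_hours(d, w)
  expect_equal(format(kept$timestamp, "%H:%M"), c("08:40", "12:00", "17:19"))
})

test_that("prolonged SB needs 30 consecutive minutes, broken by any other state", {
  expect_equal(detect_prolonged_sb(rep("sb", 30))$prolonged_min, 30)
  expect_equal(detect_prolonged_sb(rep("sb", 29))$prolonged_min, 0)
  interrupted <- c(rep("sb", 29), "lpa", rep("sb", 29))
  expect_equal(detect_prolonged_sb(interrupted)$prolonged_min, 0)
  two <- c(rep("sb", 30), "mvpa", rep("sb", 45))
  res <- detect_prolonged_sb(two)
  expect_equal(res$prolonged_min, 75)
  expect_equal(res$bouts$length, c(30L, 45L))
})

test_that("prolonged-SB detection matches the brute-force run oracle", {
  set.seed(31)
  for (i in 1:200) {
    cats <- sample(c("sb", "lpa", "mvpa", "nonwear"), sample(50:400, 1),
                   replace = TRUE, prob = c(0.75, 0.12, 0.05, 0.08))
    expect_equal(detect_prolonged_sb(cats)$prolonged_min,
                 oracle_prolonged_min(cats, 30))
  }
})

test_that("day summaries conserve categories and apply the 10-h validity rule", {
  base <- as.POSIXct("2023-05-01 07:00:00", tz = "UTC")  # a Monday
  mk_day <- function(n_wear, id) {
    tibble::tibble(participant_id = id, group = "control", phase = "pre",
                   timestamp = base + (seq_len(n_wear) - 1) * 60,
                   met = runif(n_wear, 0.5, 4))
  }
  set.seed(41)
  d <- summarize_day(rbind(mk_day(600, "a"), mk_day(599, "b")))
  expect_true(d$valid_day[d$participant_id == "a"])
  expect_false(d$valid_day[d$participant_id == "b"])
  expect_equal(d$sb_min_allday + d$lpa_min_allday + d$mvpa_min_allday,
               d$wear_min_allday)
  expect_equal(d$sb_min_working + d$lpa_min_working + d$mvpa_min_working,
               d$wear_min_working)
  expect_equal(d$total_pa_min_working, d$lpa_min_working + d$mvpa_min_working)
  # window conservation: all-day >= working-hours for every duration metric
  for (m in c("wear_min", "sb_min", "lpa_min", "mvpa_min", "total_pa_min",
              "prolonged_sb_min")) {
    expect_true(all(d[[paste0(m, "_allday")]] >= d[[paste0(m, "_working")]]))
  }
  # zero-epoch input
  empty <- summarize_day(mk_day(600, "a")[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("weekend days are flagged", {
  sat <- tibble::tibble(
    participant_id = "a", group = "control", phase = "pre",
    timestamp = as.POSIXct("2023-05-06 08:00:00", tz = "UTC") + (0:99) * 60,
    met = 1)
  expect_true(all(summarize_day(sat)$weekend))
})

test_that("working-hours normalization follows observed/wearing x 520", {
  expect_equal(normalize_to_working_hours(260, 520), 260)
  expect_equal(normalize_to_working_hours(250, 500), 260)
  expect_error(normalize_to_working_hours(10, 0), "wearing_min must be positive")
  expect_error(normalize_to_working_hours(30, 20), "observed_min")
  # scale property: uniform rescaling of the composition leaves values fixed
  obs <- c(200, 100, 50); wear <- sum(obs)
  expect_equal(normalize_to_working_hours(obs * 0.8, wear * 0.8),
               normalize_to_working_hours(obs, wear))
})

test_that("normalization identities hold on simulated phase summaries", {
  ph <- summarize_phase(summarize_day(simulate_cohort(small_config(5))))
  expect_equal(ph$sb_norm + ph$total_pa_norm, rep(520, nrow(ph)))
  expect_equal(ph$lpa_norm + ph$mvpa_norm, ph$total_pa_norm)
  # all-day means stay raw: SB + total PA = all-day wear
  expect_equal(ph$sb_min_allday + ph$total_pa_min_allday, ph$wear_min_allday)
})

test_that("valid-participant filtering matches hand enumeration", {
  mk <- function(id, phase, dates, valid) {
    tibble::tibble(participant_id = id, group = "control", phase = phase,
                   date = as.Date(dates), weekend = FALSE, valid_day = valid)
  }
  week1 <- as.character(as.Date("2023-05-01") + 0:4)  # Mon-Fri
  week2 <- as.character(as.Date("2023-05-08") + 0:4)
  days <- rbind(
    mk("p1", "pre", c(week1, week2), rep(TRUE, 10)),            # retained
    mk("p2", "pre", c(week1, week2), c(rep(TRUE, 4), FALSE,
                                       rep(TRUE, 4), FALSE)),   # 4 + 4
    mk("p3", "pre", c(week1, week2), c(rep(TRUE, 3), FALSE, FALSE,
                                       rep(TRUE, 5))),          # 3 in week 1
    mk("p4", "pre", week1, c(TRUE, TRUE, TRUE, FALSE, FALSE))   # 3 overall
  )
  per_week <- filter_valid_participants(days, week_rule = "per-week")
  expect_equal(per_week$retained[match(paste0("p", 1:4),
                                       per_week$participant_id)],
               c(TRUE, TRUE, FALSE, FALSE))
  overall <- filter_valid_participants(days, week_rule = "overall")
  expect_equal(overall$retained[match(paste0("p", 1:4),
                                      overall$participant_id)],
               c(TRUE, TRUE, TRUE, FALSE))
})

test_that("phase summaries average valid days and office time correctly", {
  base <- as.POSIXct("2023-05-01 07:00:00", tz = "UTC")
  mk_day <- function(day_offset, met) {
    tibble::tibble(participant_id = "a", group = "control", phase = "pre",
                   timestamp = base + day_offset * 86400 +
                     (seq_along(met) - 1) * 60,
                   met = met)
  }
  set.seed(51)
  epochs <- dplyr::bind_rows(lapply(0:4, function(i) {
    mk_day(i, runif(700, 0.5, 4))
  }))
  ee <- tibble::tibble(participant_id = "a", group = "control", phase = "pre",
                       date = as.Date("2023-05-01"),
                       entry_time = c("09:00", "13:00"),
                       exit_time = c("12:00", "16:00"))
  ph <- summarize_phase(summarize_day(epochs), ee)
  expect_equal(ph$n_valid_days, 5)
  expect_equal(ph$time_in_office_h, 6)
  # per-day normalization then averaging
  d <- summarize_day(epochs)
  expect_equal(ph$sb_norm,
               mean(d$sb_min_working / d$wear_min_working * 520))
  expect_error(summarize_phase(summarize_day(mk_day(0, runif(100, 0.5, 4)))),
               "no valid days")
})

test_that("entry/exit intervals with exit before entry are rejected", {
  ee <- tibble::tibble(participant_id = "a", phase = "pre",
                       date = as.Date("2023-05-01"),
                       entry_time = "10:00", exit_time = "09:00")
  expect_error(time_in_office(ee), "exit_time must be after entry_time")
})
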