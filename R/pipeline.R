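#' End-to-end pipeline configuration
#'
#' Bundles the simulation configurations and analysis options that drive
#' [run_pipeline()].
#'
#' @param accel an [accel_sim_config()].
#' @param video_seed seed for the detection-log generators (both layouts).
#' @param mean_office_hours mean daily in-office hours for the entry/exit
#'   generator.
#' @param window a [working_window()].
#' @param alpha significance level for interaction gating (default 0.05).
#' @param min_valid_days,week_rule valid-participant rule (see
#'   [filter_valid_participants()]).
#' @param intensity_scale multiplier on [default_zone_intensities()]
#'   (scale down for quick runs).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(accel, video_seed = accel$seed + 5000L,
                            mean_office_hours = 7,
                            window = working_window(), alpha = 0.05,
                            min_valid_days = 4,
                            week_rule = c("per-week", "overall"),
                            intensity_scale = 1) {
  stopifnot(inherits(accel, "accel_sim_config"),
            inherits(window, "working_window"), intensity_scale > 0)
  structure(
    list(accel = accel, video_seed = as.integer(video_seed),
         mean_office_hours = mean_office_hours, window = window,
         alpha = alpha, min_valid_days = min_valid_days,
         week_rule = match.arg(week_rule),
         intensity_scale = intensity_scale),
    class = "pipeline_config"
  )
}

pipeline_paths <- function(out_dir) {
  list(
    epochs = file.path(out_dir, "epochs.csv"),
    entry_exit = file.path(out_dir, "entry_exit.csv"),
    plan_pre = file.path(out_dir, "plan_pre.geojson"),
    plan_post = file.path(out_dir, "plan_post.geojson"),
    detections_pre = file.path(out_dir, "detections_pre.csv"),
    detections_post = file.path(out_dir, "detections_post.csv"),
    day_summaries = file.path(out_dir, "day_summaries.csv"),
    phase_summaries = file.path(out_dir, "phase_summaries.csv"),
    slot_counts_pre = file.path(out_dir, "slot_counts_pre.csv"),
    slot_counts_post = file.path(out_dir, "slot_counts_post.csv"),
    table1 = file.path(out_dir, "table_baseline.csv"),
    table2 = file.path(out_dir, "table_activity_change.csv"),
    table3 = file.path(out_dir, "table_space_utilization.csv"),
    anova_json = file.path(out_dir, "anova_results.json"),
    figure = file.path(out_dir, "figure_slot_profiles.png")
  )
}

#' Run the simulate / process / analyze / report pipeline
#'
#' Executes the requested steps in order, writing every artifact under
#' `out_dir` and returning a manifest of files with MD5 content hashes.
#' With a fixed configuration (seeds included) the manifest hashes are
#' identical across runs.
#'
#' Steps: `simulate` (epoch, entry/exit, plan and detection files), `accel`
#' (day and phase summaries), `video` (slot counts per layout), `anova`
#' (activity-change and space ANOVA results), `report` (baseline,
#' activity-change and space-utilization tables plus the shared-workstation
#' slot-profile figure).
#'
#' @param config a [pipeline_config()].
#' @param steps ordered subset of
#'   `c("simulate", "accel", "video", "anova", "report")`.
#' @param out_dir output directory (created if missing).
#' @return tibble manifest (`file`, `md5`), invisibly also attached as the
#'   `manifest` attribute of the returned object.
#' @export
run_pipeline <- function(config,
                         steps = c("simulate", "accel", "video", "anova",
                                   "report"),
                         out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  steps <- match.arg(steps, several.ok = TRUE)
  if (missing(out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- pipeline_paths(out_dir)
  written <- character(0)
  need <- function(path, what) {
    if (!file.exists(path)) {
      stop(sprintf("missing input for step '%s': %s", what, path),
           call. = FALSE)
    }
  }

  if ("simulate" %in% steps) {
    message("step simulate: generating cohort, logs, plans and detections")
    epochs <- simulate_cohort(config$accel)
    write_epoch_csv(epochs, p$epochs)
    write_entry_exit_csv(
      simulate_entry_exit(config$accel, config$mean_office_hours),
      p$entry_exit)
    for (layout in c("pre", "post")) {
      plan <- office_plan(layout)
      plan_path <- if (layout == "pre") p$plan_pre else p$plan_post
      det_path <- if (layout == "pre") p$detections_pre else p$detections_post
      write_plan_geojson(plan, plan_path)
      vconf <- video_sim_config(
        default_zone_intensities(plan) * config$intensity_scale,
        seed = config$video_seed + match(layout, c("pre", "post")))
      write_detection_csv(simulate_detections(plan, vconf), det_path)
      written <- c(written, plan_path, det_path)
    }
    written <- c(written, p$epochs, p$entry_exit)
  }

  if ("accel" %in% steps) {
    need(p$epochs, "accel"); need(p$entry_exit, "accel")
    message("step accel: summarizing epochs into day and phase tables")
    epochs <- read_epoch_csv(p$epochs)
    entry_exit <- read_entry_exit_csv(p$entry_exit)
    days <- summarize_day(epochs, config$window)
    retained <- filter_valid_participants(days, config$min_valid_days,
                                          config$week_rule)
    n_excluded <- sum(!retained$retained)
    message(sprintf("  %d participant-phase(s) excluded by the valid-day rule",
                    n_excluded))
    phases <- summarize_phase(days, entry_exit, config$window,
                              config$min_valid_days, config$week_rule)
    readr::write_csv(days, p$day_summaries)
    readr::write_csv(phases, p$phase_summaries)
    written <- c(written, p$day_summaries, p$phase_summaries)
  }

  if ("video" %in% steps) {
    message("step video: aggregating detections into slot counts")
    for (layout in c("pre", "post")) {
      plan_path <- if (layout == "pre") p$plan_pre else p$plan_post
      det_path <- if (layout == "pre") p$detections_pre else p$detections_post
      out_path <- if (layout == "pre") p$slot_counts_pre else p$slot_counts_post
      need(plan_path, "video"); need(det_path, "video")
      plan <- read_plan_geojson(plan_path)
      log <- read_detection_csv(det_path)
      counts <- aggregate_slot_counts(log, plan)
      readr::write_csv(counts, out_path)
      written <- c(written, out_path)
    }
  }

  if ("anova" %in% steps) {
    need(p$phase_summaries, "anova")
    message("step anova: activity-change and space-utilization models")
    phases <- readr::read_csv(p$phase_summaries, show_col_types = FALSE)
    results <- activity_anova_results(phases, config$alpha)
    space <- list()
    for (layout in c("pre", "post")) {
      sc_path <- if (layout == "pre") p$slot_counts_pre else p$slot_counts_post
      need(sc_path, "anova")
      counts <- readr::read_csv(sc_path, show_col_types = FALSE)
      plan <- read_plan_geojson(if (layout == "pre") p$plan_pre else
                                  p$plan_post)
      space[[layout]] <- space_anova_results(counts, plan)
    }
    jsonlite::write_json(
      list(activity = lapply(results, anova_result_json),
           space = lapply(space, function(x) lapply(x, anova_result_json))),
      p$anova_json, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    written <- c(written, p$anova_json)
  }

  if ("report" %in% steps) {
    need(p$phase_summaries, "report")
    need(p$slot_counts_pre, "report"); need(p$slot_counts_post, "report")
    message("step report: rendering tables and slot-profile figure")
    phases <- readr::read_csv(p$phase_summaries, show_col_types = FALSE)
    counts_post <- readr::read_csv(p$slot_counts_post, show_col_types = FALSE)
    counts_pre <- readr::read_csv(p$slot_counts_pre, show_col_types = FALSE)
    written <- c(written,
                 render_tables(phases, counts_pre, counts_post, p,
                               alpha = config$alpha))
  }

  written <- unique(written)
  manifest <- tibble::tibble(
    file = basename(written),
    md5 = unname(tools::md5sum(written))
  )
  manifest
}

# the repeated-measures metric family of an activity-change table
activity_metrics <- function() {
  c("sb_norm", "prolonged_sb_norm", "total_pa_norm", "lpa_norm", "mvpa_norm",
    "sb_min_allday", "prolonged_sb_min_allday", "total_pa_min_allday",
    "lpa_min_allday", "mvpa_min_allday")
}

activity_anova_results <- function(phases, alpha = 0.05) {
  phases$phase <- factor(phases$phase, levels = c("pre", "post"))
  out <- list()
  for (m in intersect(activity_metrics(), names(phases))) {
    fit <- mixed_anova(phases, m, "participant_id", "group", "phase")
    out[[m]] <- list(fit = fit, posthoc = bonferroni_posthoc(fit, alpha))
  }
  if ("time_in_office_h" %in% names(phases) &&
      !anyNA(phases$time_in_office_h)) {
    fit <- mixed_anova(phases, "time_in_office_h", "participant_id", "group",
                       "phase")
    out[["time_in_office_h"]] <- list(fit = fit,
                                      posthoc = bonferroni_posthoc(fit, alpha))
  }
  out
}

# space x slot split-plot per space family, day-within-space as the subject;
# aisle analysis adjusts for zone area
space_anova_results <- function(slot_counts, plan) {
  aisles <- c("main_aisle", "around_workstation_aisle", "multiple_usage_aisle")
  res <- list()
  for (fam in c("aisle", "workstation")) {
    cats <- if (fam == "aisle") aisles else
      c("dedicated_workstation", "shared_workstation")
    sub <- slot_counts[slot_counts$category %in% cats, , drop = FALSE]
    if (nrow(sub) == 0L) next
    sub$unit <- paste(sub$label, sub$day_index, sep = "/")
    sub <- dplyr::left_join(sub, plan[, c("label", "area_m2")], by = "label")
    plain <- function() mixed_anova(sub, "count", "unit", "label",
                                    "slot_index")
    res[[fam]] <- tryCatch({
      if (fam == "aisle") {
        # area-adjusted when the covariate is estimable next to the space
        # factor (needs >= 3 zones); otherwise fall back unadjusted
        tryCatch(
          list(fit = withCallingHandlers(
            mixed_ancova(sub, "count", "unit", "label", "slot_index",
                         "area_m2"),
            warning = function(w) invokeRestart("muffleWarning")),
            note = NULL),
          error = function(e) list(
            fit = plain(),
            note = paste("area covariate not estimable; unadjusted model:",
                         conditionMessage(e))))
      } else {
        list(fit = plain(), note = NULL)
      }
    }, error = function(e) {
      list(fit = NULL, note = paste("statistical analysis not applicable:",
                                    conditionMessage(e)))
    })
  }
  res
}

anova_result_json <- function(x) {
  if (!is.null(x$note) && is.null(x$fit)) return(list(note = x$note))
  out <- list(table = x$fit$table)
  if (!is.null(x$note)) out$note <- x$note
  if (!is.null(x$posthoc)) {
    out$posthoc <- x$posthoc
    nt <- attr(x$posthoc, "note")
    if (!is.null(nt)) out$posthoc_note <- nt
  }
  if (!is.null(x$fit$sphericity_note)) {
    out$sphericity_note <- x$fit$sphericity_note
  }
  out
}
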