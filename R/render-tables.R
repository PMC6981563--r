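fmt_mean_sd <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))

metric_rows <- function() {
  tibble::tibble(
    metric = activity_metrics(),
    window = rep(c("working_hours", "all_day"), each = 5),
    row_name = rep(c("SB time", "Prolonged SB time", "Total PA",
                     "Light-intensity PA",
                     "Moderate- to vigorous-intensity PA"), 2)
  )
}

#' Render report tables and the slot-profile figure
#'
#' Writes the three standard outputs of the analysis: a baseline table
#' (pre-phase activity means with group-comparison p values), an
#' activity-change table (group x phase mean ± SD per metric with
#' time-effect, interaction and post hoc p values) and a space-utilization
#' table (detections per 15-min slot per space), plus a per-zone
#' shared-workstation slot-profile figure.
#'
#' @param phases phase-summary table (see [summarize_phase()]).
#' @param counts_pre,counts_post slot-count tables per layout.
#' @param paths named list of output paths (as built inside
#'   [run_pipeline()]): `table1`, `table2`, `table3`, `figure`.
#' @param alpha interaction gate for post hoc tests.
#' @return character vector of files written.
#' @export
render_tables <- function(phases, counts_pre, counts_post, paths,
                          alpha = 0.05) {
  stopifnot(all(c("table1", "table2", "table3", "figure") %in% names(paths)))
  rows <- metric_rows()

  # baseline table: pre-phase cells + equal-variance t per metric; degenerate
  # (zero-variance) variables render a blank p rather than aborting the report
  safe_p <- function(data, v) {
    tryCatch(round(baseline_tests(data, "group", v)$p, 3),
             error = function(e) NA_real_)
  }
  pre <- phases[phases$phase == "pre", , drop = FALSE]
  t1 <- dplyr::bind_rows(lapply(seq_len(nrow(rows)), function(i) {
    m <- rows$metric[i]
    tibble::tibble(
      variable = rows$row_name[i], window = rows$window[i],
      control = fmt_mean_sd(pre[[m]][pre$group == "control"]),
      renovation = fmt_mean_sd(pre[[m]][pre$group == "renovation"]),
      p_value = safe_p(pre, m)
    )
  }))
  t1 <- dplyr::bind_rows(
    tibble::tibble(variable = "Number of valid days", window = "all_day",
                   control = fmt_mean_sd(pre$n_valid_days[pre$group == "control"]),
                   renovation = fmt_mean_sd(pre$n_valid_days[pre$group == "renovation"]),
                   p_value = safe_p(pre, "n_valid_days")),
    t1)
  readr::write_csv(t1, paths$table1, na = "")

  # activity-change table
  res <- activity_anova_results(phases, alpha)
  t2 <- dplyr::bind_rows(lapply(seq_len(nrow(rows)), function(i) {
    m <- rows$metric[i]
    r <- res[[m]]
    cell <- function(g, p) {
      fmt_mean_sd(phases[[m]][phases$group == g & phases$phase == p])
    }
    ph <- r$posthoc
    ph_p <- function(g) {
      if (nrow(ph) == 0) return(NA_real_)
      v <- ph$p_adj[ph$level == g & grepl("pre vs post", ph$contrast)]
      if (length(v) == 0) NA_real_ else round(v[1], 3)
    }
    tab <- r$fit$table
    dplyr::bind_rows(
      tibble::tibble(
        variable = rows$row_name[i], window = rows$window[i],
        group = c("control", "renovation"),
        pre = c(cell("control", "pre"), cell("renovation", "pre")),
        post = c(cell("control", "post"), cell("renovation", "post")),
        time_p = c(round(tab$p[tab$effect == "within"], 3), NA),
        interaction_p = c(round(tab$p[tab$effect == "interaction"], 3), NA),
        posthoc_p = c(ph_p("control"), ph_p("renovation"))
      )
    )
  }))
  # empty post hoc families render as blank cells, not zeros
  readr::write_csv(t2, paths$table2, na = "")

  # space-utilization table, one block per layout
  t3 <- dplyr::bind_rows(
    dplyr::mutate(summarize_space(counts_pre), layout = "pre"),
    dplyr::mutate(summarize_space(counts_post), layout = "post")
  )
  t3 <- t3[, c("layout", "space", "category", "mean_per_slot", "se",
               "n_cells")]
  readr::write_csv(t3, paths$table3)

  # shared-workstation slot profiles (post layout)
  prof <- slot_profile(counts_post)
  fig <- ggplot2::ggplot(
    prof[prof$series != "mean", ],
    ggplot2::aes(x = .data$slot_index, y = .data$count,
                 colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = prof[prof$series == "mean", ],
                       colour = "black", linewidth = 1) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "15-min slot (from 10:00)",
                  y = "detections per slot",
                  colour = NULL,
                  title = "Shared-workstation utilization by time slot") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(paths$figure, fig, width = 8, height = 6, dpi = 120)

  c(paths$table1, paths$table2, paths$table3, paths$figure)
}
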