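#' Split-plot (mixed) repeated-measures ANOVA
#'
#' Classical two-stratum decomposition for a design with one between-subjects
#' factor (e.g. renovation vs control group, or office space) and one
#' within-subjects repeated factor (e.g. pre/post phase, or 15-min time
#' slot). The between-subjects stratum tests the between effect against
#' subject-within-group variation; the within-subjects stratum tests the
#' within effect and the interaction against the subject x within residual.
#' Group sizes may be unequal; the design must be complete within subjects
#' (every subject observed at every within level) — incomplete subjects are
#' dropped listwise with a warning.
#'
#' No sphericity correction is applied; with more than two within levels the
#' result carries a `sphericity_note` flagging this.
#'
#' @param data data frame of observations, one row per subject x within
#'   level.
#' @param response,subject,between,within column names (strings).
#' @return object of class `mixed_anova`: a list with `table` (tibble of
#'   effect, ss, df, ms, f, p), `strata`, `n_subjects`, `dropped_subjects`,
#'   the design columns (for post hoc tests) and possibly
#'   `sphericity_note`.
#' @examples
#' d <- expand.grid(subject = 1:6, time = c("pre", "post"))
#' d$group <- ifelse(d$subject <= 3, "a", "b")
#' d$y <- rnorm(12)
#' mixed_anova(d, "y", "subject", "group", "time")
#' @export
mixed_anova <- function(data, response, subject, between, within) {
  d <- prepare_split_plot(data, response, subject, between, within)
  res <- split_plot_ss(d$y, d$subject, d$between, d$within)

  a <- nlevels(d$between); t_lev <- nlevels(d$within); N <- d$n_subjects
  df_between <- a - 1L
  df_sub_err <- N - a
  df_within <- t_lev - 1L
  df_inter <- (a - 1L) * (t_lev - 1L)
  df_win_err <- (N - a) * (t_lev - 1L)

  if (res$ss_total < 1e-12) {
    stop("degenerate design: all responses identical (zero total SS)",
         call. = FALSE)
  }
  tab <- anova_table(
    effect = c("between", "subject_error", "within", "interaction",
               "within_error"),
    ss = c(res$ss_between, res$ss_sub_err, res$ss_within, res$ss_inter,
           res$ss_win_err),
    df = c(df_between, df_sub_err, df_within, df_inter, df_win_err),
    err = c("subject_error", NA, "within_error", "within_error", NA)
  )
  out <- list(table = tab, strata = list(
    between = c(error = "subject_error"),
    within = c(error = "within_error")),
    n_subjects = N, dropped_subjects = d$dropped,
    data = tibble::tibble(y = d$y, subject = d$subject,
                          between = d$between, within = d$within))
  if (t_lev > 2L) {
    out$sphericity_note <-
      "no sphericity correction applied; interpret within-stratum p with care"
  }
  class(out) <- "mixed_anova"
  out
}

# shared validation + listwise deletion for split-plot designs
prepare_split_plot <- function(data, response, subject, between, within,
                               covariate = NULL) {
  cols <- c(response, subject, between, within, covariate)
  if (!all(cols %in% names(data))) {
    stop("missing column(s): ",
         paste(setdiff(cols, names(data)), collapse = ", "), call. = FALSE)
  }
  y <- data[[response]]
  s <- factor(data[[subject]])
  g <- factor(data[[between]])
  w <- factor(data[[within]])
  if (anyNA(y) || anyNA(s) || anyNA(g) || anyNA(w)) {
    stop("missing values in design columns", call. = FALSE)
  }
  # each subject in exactly one between level
  gl <- tapply(as.character(g), s, function(z) length(unique(z)))
  if (any(gl > 1)) {
    stop("subject(s) appear in more than one between level", call. = FALSE)
  }
  # at most one observation per subject x within cell
  if (any(table(s, w) > 1)) {
    stop("more than one observation per subject x within cell", call. = FALSE)
  }
  # listwise-drop subjects missing a within level
  n_w <- nlevels(w)
  cnt <- table(s)[tapply(seq_along(s), s, length) >= 0]
  per_sub <- tapply(as.character(w), s, function(z) length(unique(z)))
  incomplete <- names(per_sub)[per_sub < n_w]
  if (length(incomplete)) {
    warning(sprintf("dropping %d subject(s) missing a within level: %s",
                    length(incomplete), paste(incomplete, collapse = ", ")),
            call. = FALSE)
    keep <- !(as.character(s) %in% incomplete)
    y <- y[keep]; s <- droplevels(s[keep]); g <- droplevels(g[keep])
    w <- droplevels(w[keep])
    if (!is.null(covariate)) data <- data[keep, , drop = FALSE]
  }
  if (nlevels(g) < 2) {
    stop("analysis not applicable: fewer than 2 between levels", call. = FALSE)
  }
  n_per_group <- tapply(as.character(s), g, function(z) length(unique(z)))
  if (any(n_per_group < 2)) {
    stop("analysis not applicable: a between level has fewer than 2 subjects",
         call. = FALSE)
  }
  cov_val <- NULL
  if (!is.null(covariate)) {
    cv <- data[[covariate]]
    if (anyNA(cv)) stop("missing covariate values", call. = FALSE)
    spread <- tapply(cv, s, function(z) diff(range(z)))
    if (any(spread > 1e-10)) {
      stop("covariate must be constant within subject", call. = FALSE)
    }
    cov_val <- cv
  }
  list(y = y, subject = s, between = g, within = w, covariate = cov_val,
       n_subjects = nlevels(s), dropped = incomplete)
}

# classical stratum sums of squares; exact for complete-within designs with
# (possibly unequal) group sizes, which are proportional and hence orthogonal
split_plot_ss <- function(y, s, g, w) {
  t_lev <- nlevels(w)
  grand <- mean(y)
  sub_means <- tapply(y, s, mean)
  sub_group <- tapply(as.character(g), s, function(z) z[1])
  n_per_group <- table(sub_group)
  g_means <- tapply(sub_means, sub_group, mean)
  w_means <- tapply(y, w, mean)
  cell_means <- tapply(y, list(g, w), mean)

  ss_between <- t_lev * sum(n_per_group * (g_means - grand)^2)
  ss_sub_err <- t_lev * sum((sub_means - g_means[sub_group])^2)
  ss_within <- length(sub_means) * sum((w_means - grand)^2)
  dev <- sweep(sweep(cell_means, 1, g_means[rownames(cell_means)]),
               2, w_means) + grand
  ss_inter <- sum(as.numeric(n_per_group[rownames(cell_means)]) * dev^2)
  ss_total <- sum((y - grand)^2)
  ss_win_err <- ss_total - ss_between - ss_sub_err - ss_within - ss_inter
  list(ss_between = ss_between, ss_sub_err = ss_sub_err,
       ss_within = ss_within, ss_inter = ss_inter,
       ss_win_err = max(ss_win_err, 0), ss_total = ss_total)
}

# assemble an ANOVA table, testing each testable effect against its error row
anova_table <- function(effect, ss, df, err) {
  ms <- ifelse(df > 0, ss / df, NA_real_)
  f <- p <- rep(NA_real_, length(effect))
  for (i in seq_along(effect)) {
    if (is.na(err[i])) next
    j <- match(err[i], effect)
    if (df[i] > 0 && df[j] > 0 && ms[j] > 0) {
      f[i] <- ms[i] / ms[j]
      p[i] <- stats::pf(f[i], df[i], df[j], lower.tail = FALSE)
    }
  }
  tibble::tibble(effect = effect, ss = ss, df = as.integer(df), ms = ms,
                 f = f, p = p)
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("split-plot ANOVA: %d subjects\n", x$n_subjects))
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  if (!is.null(x$sphericity_note)) cat("note:", x$sphericity_note, "\n")
  invisible(x)
}

#' Split-plot ANOVA with a subject-level covariate
#'
#' As [mixed_anova()], but the between-subjects stratum is adjusted for a
#' covariate that is constant within subject (e.g. zone area in a
#' space x time-slot occupancy analysis): on the subject means, the covariate
#' is fitted before the between factor (sequential decomposition), removing
#' its sum of squares from the between-subjects error before the between
#' effect is tested. The within-subjects stratum is unchanged — a
#' subject-constant covariate cannot carry within-subject information.
#'
#' When the covariate is itself constant within every between level it is
#' partially or fully aliased with the between factor: fully aliased designs
#' (no between df left) raise an error naming the aliasing, partially
#' aliased ones proceed with reduced between df and a warning.
#'
#' @inheritParams mixed_anova
#' @param covariate column name of the subject-level covariate.
#' @return object of class `mixed_anova` whose between stratum has
#'   `covariate`, `between` and `subject_error` rows.
#' @export
mixed_ancova <- function(data, response, subject, between, within, covariate) {
  d <- prepare_split_plot(data, response, subject, between, within, covariate)
  t_lev <- nlevels(d$within); N <- d$n_subjects
  res <- split_plot_ss(d$y, d$subject, d$between, d$within)

  sub_means <- tapply(d$y, d$subject, mean)
  sub_group <- factor(tapply(as.character(d$between), d$subject,
                             function(z) z[1]),
                      levels = levels(d$between))
  sub_cov <- tapply(d$covariate, d$subject, function(z) z[1])

  fit <- stats::lm(sub_means ~ sub_cov + sub_group)
  aliased <- is.na(stats::coef(fit))
  n_group_terms <- sum(grepl("^sub_group", names(stats::coef(fit))))
  n_group_est <- sum(!aliased[grepl("^sub_group", names(aliased))])
  if (n_group_est == 0L) {
    stop("covariate is aliased with the between factor (identical grouping); ",
         "between effect not estimable", call. = FALSE)
  }
  if (n_group_est < n_group_terms) {
    warning("covariate partially aliased with the between factor; ",
            "between df reduced", call. = FALSE)
  }
  an <- stats::anova(fit)
  # subject-mean SS are on the subject scale; x t_lev for the epoch scale
  ss_cov <- an["sub_cov", "Sum Sq"] * t_lev
  ss_between <- an["sub_group", "Sum Sq"] * t_lev
  df_between <- an["sub_group", "Df"]
  ss_sub_err <- an["Residuals", "Sum Sq"] * t_lev
  df_sub_err <- an["Residuals", "Df"]

  if (res$ss_total < 1e-12) {
    stop("degenerate design: all responses identical (zero total SS)",
         call. = FALSE)
  }
  tab <- anova_table(
    effect = c("covariate", "between", "subject_error", "within",
               "interaction", "within_error"),
    ss = c(ss_cov, ss_between, ss_sub_err, res$ss_within, res$ss_inter,
           res$ss_win_err),
    df = c(1L, df_between, df_sub_err, t_lev - 1L,
           (nlevels(d$between) - 1L) * (t_lev - 1L), (N - nlevels(d$between)) * (t_lev - 1L)),
    err = c("subject_error", "subject_error", NA, "within_error",
            "within_error", NA)
  )
  out <- list(table = tab, strata = list(
    between = c(error = "subject_error"),
    within = c(error = "within_error")),
    n_subjects = N, dropped_subjects = d$dropped,
    data = tibble::tibble(y = d$y, subject = d$subject,
                          between = d$between, within = d$within,
                          covariate = d$covariate))
  if (t_lev > 2L) {
    out$sphericity_note <-
      "no sphericity correction applied; interpret within-stratum p with care"
  }
  class(out) <- "mixed_anova"
  out
}

#' Bonferroni post hoc pre/post contrasts
#'
#' When the interaction is significant, performs the paired within-subject
#' contrast between within levels inside each between level (the pre- vs
#' post-test column of a group x time table) and Bonferroni-adjusts across
#' the family; optionally also the between-group contrast at each within
#' level.
#'
#' @param fit a [mixed_anova()] result.
#' @param alpha interaction significance gate (default 0.05).
#' @param family `"within-group"` (default: pre vs post inside each group) or
#'   `"both"` (additionally group contrasts at each within level, by
#'   two-sample t).
#' @return tibble of contrasts with `t`, `df`, `p_raw`, `p_adj` (
#'   `min(1, p_raw * m)`) and `m`; zero rows (with a `note` attribute) when
#'   the interaction is not significant.
#' @export
bonferroni_posthoc <- function(fit, alpha = 0.05,
                               family = c("within-group", "both")) {
  stopifnot(inherits(fit, "mixed_anova"))
  family <- match.arg(family)
  p_int <- fit$table$p[fit$table$effect == "interaction"]
  empty <- tibble::tibble(contrast = character(), level = character(),
                          estimate = numeric(), t = numeric(), df = numeric(),
                          p_raw = numeric(), p_adj = numeric(), m = integer())
  if (!is.finite(p_int) || p_int >= alpha) {
    attr(empty, "note") <- sprintf(
      "interaction p = %.3f >= alpha = %g; no post hoc tests run", p_int, alpha)
    return(empty)
  }
  d <- fit$data
  w_lev <- levels(d$within)
  rows <- list()
  for (g in levels(d$between)) {
    dg <- d[d$between == g, , drop = FALSE]
    for (i in seq_len(length(w_lev) - 1)) {
      for (j in seq((i + 1), length(w_lev))) {
        wide <- merge(dg[dg$within == w_lev[i], c("subject", "y")],
                      dg[dg$within == w_lev[j], c("subject", "y")],
                      by = "subject")
        diffs <- wide$y.x - wide$y.y
        tt <- stats::t.test(diffs)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          contrast = sprintf("%s vs %s", w_lev[i], w_lev[j]), level = g,
          estimate = mean(diffs), t = unname(tt$statistic),
          df = unname(tt$parameter), p_raw = tt$p.value)
      }
    }
  }
  if (family == "both") {
    g_lev <- levels(d$between)
    for (w in w_lev) {
      dw <- d[d$within == w, , drop = FALSE]
      for (i in seq_len(length(g_lev) - 1)) {
        for (j in seq((i + 1), length(g_lev))) {
          tt <- stats::t.test(dw$y[dw$between == g_lev[i]],
                              dw$y[dw$between == g_lev[j]], var.equal = TRUE)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            contrast = sprintf("%s vs %s", g_lev[i], g_lev[j]), level = w,
            estimate = unname(diff(rev(tt$estimate))),
            t = unname(tt$statistic), df = unname(tt$parameter),
            p_raw = tt$p.value)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$m <- nrow(out)
  out$p_adj <- pmin(1, out$p_raw * out$m)
  out[, c("contrast", "level", "estimate", "t", "df", "p_raw", "p_adj", "m")]
}

#' Baseline group comparisons
#'
#' Two-sided comparisons of baseline variables between two groups:
#' equal-variance independent t-test for numeric variables, Pearson
#' chi-square without continuity correction for categorical ones.
#'
#' @param data data frame of one row per participant.
#' @param group column name of the two-level grouping factor.
#' @param vars variable column names to test; defaults to all columns except
#'   `group`.
#' @return tibble `variable`, `test`, `statistic`, `df`, `p`.
#' @export
baseline_tests <- function(data, group, vars = setdiff(names(data), group)) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("group must have exactly 2 levels", call. = FALSE)
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      if (stats::var(x[g == levels(g)[1]]) == 0 &&
          stats::var(x[g == levels(g)[2]]) == 0) {
        stop(sprintf("variable '%s' has zero variance in both groups", v),
             call. = FALSE)
      }
      tt <- stats::t.test(x ~ g, var.equal = TRUE)
      tibble::tibble(variable = v, test = "t",
                     statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p = tt$p.value)
    } else {
      tab <- table(g, x)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      tibble::tibble(variable = v, test = "chisq",
                     statistic = unname(ct$statistic),
                     df = unname(ct$parameter), p = ct$p.value)
    }
  })
  dplyr::bind_rows(rows)
}

#' Expand a contingency table of counts to long observations
#'
#' Convenience for running [baseline_tests()] on published count margins.
#'
#' @param counts matrix of counts, rows = groups, columns = categories.
#' @return tibble with `group` and `value` columns, one row per count.
#' @export
counts_to_long <- function(counts) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  idx <- which(counts > 0, arr.ind = TRUE)
  dplyr::bind_rows(lapply(seq_len(nrow(idx)), function(k) {
    tibble::tibble(
      group = rownames(counts)[idx[k, 1]],
      value = colnames(counts)[idx[k, 2]],
      .rows = counts[idx[k, 1], idx[k, 2]]
    )
  }))
}
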