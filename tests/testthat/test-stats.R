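# toy split-plot design with hand-computable sums of squares:
# group A subjects (pre, post): (4,6) (6,6) (5,9); group B: (8,8) (9,9) (10,10)
# subject means 5..10, group means 6 and 9, grand mean 7.5
# SS_between = 2*(3*1.5^2*2) = 27; SS_subject_error = 2*4 = 8
# time means 7 and 8 -> SS_within = 6*0.5 = 3; cell means (5,7),(9,9) ->
# SS_interaction = 3; SS_total = 45 -> SS_within_error = 4
toy_design <- function() {
  tibble::tibble(
    subject = rep(paste0("s", 1:6), each = 2),
    group = rep(c("A", "B"), each = 6),
    time = factor(rep(c("pre", "post"), 6), levels = c("pre", "post")),
    y = c(4, 6, 6, 6, 5, 9, 8, 8, 9, 9, 10, 10))
}

test_that("split-plot ANOVA reproduces hand-computed sums of squares", {
  fit <- mixed_anova(toy_design(), "y", "subject", "group", "time")
  tab <- fit$table
  expect_equal(tab$ss[tab$effect == "between"], 27, tolerance = 1e-12)
  expect_equal(tab$ss[tab$effect == "subject_error"], 8, tolerance = 1e-12)
  expect_equal(tab$ss[tab$effect == "within"], 3, tolerance = 1e-12)
  expect_equal(tab$ss[tab$effect == "interaction"], 3, tolerance = 1e-12)
  expect_equal(tab$ss[tab$effect == "within_error"], 4, tolerance = 1e-12)
  expect_equal(tab$df, c(1L, 4L, 1L, 1L, 4L))
  expect_equal(tab$f[tab$effect == "between"], 13.5, tolerance = 1e-12)
  expect_equal(tab$f[tab$effect == "within"], 3, tolerance = 1e-12)
  expect_equal(tab$f[tab$effect == "interaction"], 3, tolerance = 1e-12)
  expect_equal(tab$p[tab$effect == "interaction"],
               pf(3, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("split-plot SS partition the total on balanced designs", {
  set.seed(111)
  for (i in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1); t_lev <- sample(2:5, 1)
    d <- tidyr::expand_grid(subject = seq_len(n1 + n2),
                            time = paste0("t", seq_len(t_lev)))
    d$group <- ifelse(d$subject <= n1, "A", "B")
    d$y <- rnorm(nrow(d))
    fit <- mixed_anova(d, "y", "subject", "group", "time")
    ss_total <- sum((d$y - mean(d$y))^2)
    expect_equal(sum(fit$table$ss), ss_total, tolerance = 1e-9)
  }
})

test_that("split-plot ANOVA agrees with the aov error-strata oracle", {
  set.seed(121)
  for (i in 1:10) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1); t_lev <- sample(2:4, 1)
    d <- tidyr::expand_grid(subject = seq_len(n1 + n2),
                            time = paste0("t", seq_len(t_lev)))
    d$group <- ifelse(d$subject <= n1, "A", "B")
    d$y <- rnorm(nrow(d)) + (d$group == "A") * 0.5 +
      (d$time == "t1") * (d$group == "B") * 0.7
    fit <- mixed_anova(d, "y", "subject", "group", "time")
    ref <- summary(stats::aov(
      y ~ group * time + Error(factor(subject) / time), data = d))
    b <- ref[["Error: factor(subject)"]][[1]]
    w <- ref[["Error: factor(subject):time"]][[1]]
    tab <- fit$table
    expect_equal(tab$ss[tab$effect == "between"], b["group", "Sum Sq"],
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(tab$f[tab$effect == "within"], w["time", "F value"],
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(tab$p[tab$effect == "interaction"],
                 w["group:time", "Pr(>F)"], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate and inapplicable designs raise informative errors", {
  d <- toy_design()
  d$y <- 5
  expect_error(mixed_anova(d, "y", "subject", "group", "time"), "degenerate")
  one_sub <- toy_design()[c(1:6, 7:8), ]  # group B has a single subject
  expect_error(mixed_anova(one_sub, "y", "subject", "group", "time"),
               "not applicable")
  # incomplete subject dropped listwise with warning
  incomplete <- toy_design()[-2, ]
  expect_warning(fit <- mixed_anova(incomplete, "y", "subject", "group",
                                    "time"),
                 "dropping 1 subject")
  expect_equal(fit$n_subjects, 5)
})

test_that("null covariate leaves the between-effect F unchanged", {
  d <- toy_design()
  set.seed(131)
  cov_by_sub <- rnorm(6)
  d$area <- cov_by_sub[as.integer(factor(d$subject))]
  plain <- mixed_anova(d, "y", "subject", "group", "time")
  # orthogonalize the covariate against subject means and group so its slope
  # is 0 by construction
  sub_means <- tapply(d$y, d$subject, mean)
  g_sub <- factor(rep(c("A", "B"), each = 3))
  r <- resid(lm(cov_by_sub ~ g_sub + sub_means))
  d$area0 <- r[as.integer(factor(d$subject))]
  adj <- mixed_ancova(d, "y", "subject", "group", "time", "area0")
  # null covariate: zero covariate SS, between and error SS unchanged
  expect_equal(adj$table$ss[adj$table$effect == "covariate"], 0,
               tolerance = 1e-9)
  expect_equal(adj$table$ss[adj$table$effect == "between"],
               plain$table$ss[plain$table$effect == "between"],
               tolerance = 1e-8)
  expect_equal(adj$table$ss[adj$table$effect == "subject_error"],
               plain$table$ss[plain$table$effect == "subject_error"],
               tolerance = 1e-8)
})

test_that("covariate adjustment matches the residualization oracle", {
  set.seed(141)
  n <- 14
  d <- tidyr::expand_grid(subject = seq_len(n), time = c("pre", "post"))
  d$group <- ifelse(d$subject <= 6, "A", "B")
  cov_by_sub <- rnorm(n)
  d$area <- cov_by_sub[d$subject]
  d$y <- rnorm(nrow(d)) + 0.9 * d$area + (d$group == "A") * 1.2
  fit <- mixed_ancova(d, "y", "subject", "group", "time", "area")
  # oracle: sequential ANCOVA on subject means (x2 for the two within levels)
  m <- tapply(d$y, d$subject, mean)
  g <- factor(ifelse(seq_len(n) <= 6, "A", "B"))
  an <- anova(lm(m ~ cov_by_sub + g))
  tab <- fit$table
  expect_equal(tab$ss[tab$effect == "covariate"], 2 * an["cov_by_sub", "Sum Sq"],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(tab$ss[tab$effect == "between"], 2 * an["g", "Sum Sq"],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(tab$ss[tab$effect == "subject_error"],
               2 * an["Residuals", "Sum Sq"], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(tab$f[tab$effect == "between"], an["g", "F value"],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("a covariate identical to the group dummy is reported as aliased", {
  d <- toy_design()
  d$area <- ifelse(d$group == "A", 1, 2)
  expect_error(mixed_ancova(d, "y", "subject", "group", "time", "area"),
               "aliased")
  d$area2 <- seq_len(nrow(d))  # varies within subject
  expect_error(mixed_ancova(d, "y", "subject", "group", "time", "area2"),
               "constant within subject")
})

test_that("Bonferroni post hoc adjusts, caps and gates on the interaction", {
  set.seed(151)
  n <- 8
  d <- tidyr::expand_grid(subject = seq_len(2 * n),
                          time = factor(c("pre", "post"),
                                        levels = c("pre", "post")))
  d$group <- ifelse(d$subject <= n, "ctl", "ren")
  d$y <- rnorm(nrow(d), sd = 0.3) +
    ifelse(d$group == "ren" & d$time == "post", -2, 0)
  fit <- mixed_anova(d, "y", "subject", "group", "time")
  ph <- bonferroni_posthoc(fit)
  expect_equal(nrow(ph), 2)
  expect_equal(ph$m, c(2L, 2L))
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 2))
  # capping at 1
  expect_true(all(ph$p_adj <= 1))
  # non-significant interaction -> empty with note
  d$y <- rnorm(nrow(d))
  fit0 <- mixed_anova(d, "y", "subject", "group", "time")
  p_int <- fit0$table$p[fit0$table$effect == "interaction"]
  expect_gte(p_int, 0.05)  # pure-noise design under the fixed seed
  ph0 <- bonferroni_posthoc(fit0)
  expect_equal(nrow(ph0), 0)
  expect_match(attr(ph0, "note"), "no post hoc tests run")
})

test_that("baseline tests use equal-variance t and uncorrected chi-square", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 6),
                      age = c(1:6, 1:6),
                      bmi = c(1:6, 3:8))
  res <- baseline_tests(d, "group", c("age", "bmi"))
  expect_equal(res$statistic[res$variable == "age"], 0)
  expect_equal(res$p[res$variable == "age"], 1)
  ref <- t.test(bmi ~ group, data = d, var.equal = TRUE)
  expect_equal(res$p[res$variable == "bmi"], ref$p.value)
  expect_error(baseline_tests(tibble::tibble(group = c("a", "a", "b", "b"),
                                             x = c(1, 1, 1, 1)), "group"),
               "zero variance")
})

test_that("chi-square statistic matches the direct O-E formula on a 2x2", {
  counts <- matrix(c(10, 4, 6, 12), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("yes", "no")))
  long <- counts_to_long(counts)
  expect_equal(nrow(long), sum(counts))
  res <- baseline_tests(long, "group", "value")
  # direct formula
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  expect_equal(res$statistic, sum((counts - E)^2 / E), tolerance = 1e-12)
})

test_that("published job-type margin yields a significant group difference", {
  # control 12 managers / 13 clerks / 4 sales; renovation 7 / 1 / 5
  counts <- matrix(c(12, 13, 4, 7, 1, 5), nrow = 2, byrow = TRUE,
                   dimnames = list(c("control", "renovation"),
                                   c("manager", "clerk", "sales")))
  res <- suppressWarnings(baseline_tests(counts_to_long(counts),
                                         "group", "value"))
  expect_equal(round(res$p, 3), 0.037)
  expect_lt(res$p, 0.05)
})

test_that("between-effect p-values are uniform under group-label permutation", {
  set.seed(161)
  n <- 10
  base <- tidyr::expand_grid(subject = seq_len(n), time = c("pre", "post"))
  p <- replicate(2000, {
    # fresh null data with subject intercepts; labels carry no signal
    base$y <- rnorm(nrow(base)) + rnorm(n)[base$subject]
    g <- sample(rep(c("A", "B"), n / 2))
    base$group <- g[base$subject]
    fit <- mixed_anova(base, "y", "subject", "group", "time")
    fit$table$p[fit$table$effect == "between"]
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
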