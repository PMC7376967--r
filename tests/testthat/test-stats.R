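# ANOVA reconstruction, studentized range, Tukey HSD, fold changes.

test_that("sd_from_sem inverts the SEM definition", {
  expect_equal(sd_from_sem(57, 5), 57 * sqrt(5))
  expect_equal(sd_from_sem(57, 5), 127.44, tolerance = 1e-4 * 127)
  expect_equal(sd_from_sem(0, 7), 0)
  x <- rnorm(10)
  expect_equal(sd_from_sem(sd(x) / sqrt(10), 10), sd(x))
})

test_that("view aggregation supports sum and mean conventions", {
  views <- expand.grid(section_index = 1:6, view_index = 1:3)
  views$animal_id <- "a1"; views$group <- "WT"
  views$region <- "SVZ"; views$marker <- "Ki67"
  views$count <- 10
  expect_equal(aggregate_views(views)$value, 180)
  views$count <- rep(c(1, 2, 3), each = 6)
  expect_equal(aggregate_views(views)$value, 36)
  expect_equal(aggregate_views(views, "mean")$value, 2)
  one <- views[1, ]; one$count <- 7
  expect_equal(aggregate_views(one)$value, 7)
  expect_error(aggregate_views(views[0, ]), "empty")
  bad <- views; bad$count[1] <- -1
  expect_error(aggregate_views(bad), "non-negative")
})

test_that("one-way ANOVA from counts matches hand computation and aov()", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  a <- anova_from_counts(g)
  expect_equal(a$F, 3)
  expect_equal(a$df_between, 2L)
  expect_equal(a$df_within, 6L)
  # identical groups: F = 0
  expect_equal(anova_from_counts(list(x = 1:4, y = 1:4))$F, 0)
  # oracle: stats::aov on seeded random data
  set.seed(42)
  for (rep in 1:5) {
    df <- data.frame(
      value = c(rnorm(5, 10), rnorm(5, 12), rnorm(5, 9)),
      group = rep(c("g1", "g2", "g3"), each = 5))
    mine <- anova_from_counts(split(df$value, df$group))
    ref <- summary(stats::aov(value ~ group, df))[[1]]
    expect_equal(mine$F, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(mine$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("summary-based ANOVA equals the raw-data path on exact summaries", {
  set.seed(7)
  for (rep in 1:10) {
    g <- lapply(1:3, function(i) rnorm(5, mean = 10 * i, sd = 3))
    summ <- data.frame(
      group = paste0("g", 1:3),
      mean = vapply(g, mean, 0),
      sem = vapply(g, function(x) sd(x) / sqrt(length(x)), 0),
      n = 5)
    a1 <- anova_from_summary(summ)
    a2 <- anova_from_counts(g)
    expect_equal(a1$F, a2$F, tolerance = 1e-10)
    expect_equal(a1$ms_within, a2$ms_within, tolerance = 1e-10)
  }
})

test_that("F is invariant under affine rescaling of the data", {
  set.seed(11)
  g <- lapply(1:3, function(i) rnorm(6, 5 * i, 2))
  f0 <- anova_from_counts(g)$F
  for (ab in list(c(2.5, 0), c(-1.3, 7), c(0.01, -4))) {
    gt <- lapply(g, function(x) ab[1] * x + ab[2])
    expect_equal(anova_from_counts(gt)$F, f0, tolerance = 1e-9)
  }
})

test_that("degenerate summaries are handled", {
  s <- data.frame(group = c("a", "b"), mean = c(3, 3), sem = c(1, 2), n = 4)
  expect_equal(anova_from_summary(s)$F, 0)
  s2 <- data.frame(group = c("a", "b"), mean = c(3, 4), sem = 0, n = 4)
  a2 <- anova_from_summary(s2)
  expect_true(is.infinite(a2$F))
  expect_equal(a2$p, 0)
  expect_error(anova_from_summary(s[1, , drop = FALSE]), "2 groups")
  mixed <- data.frame(group = c("a", "b"), mean = 1:2, sem = 1, n = 5,
                      region = c("SVZ", "hippocampus"))
  expect_error(anova_from_summary(mixed), "region")
})

test_that("studentized-range CDF matches ptukey and published critical values", {
  qs <- c(0.1, 0.5, 1, 2, 3, 3.773, 4.5, 6, 8)
  for (k in c(2, 3, 4)) for (df in c(6, 12, 20)) {
    expect_equal(studentized_range_cdf(qs, k, df), stats::ptukey(qs, k, df),
                 tolerance = 1e-4)
    # published alpha = 0.05 critical values recovered within 0.01 in q
    qcrit <- stats::qtukey(0.95, k, df)
    expect_equal(studentized_range_cdf(qcrit, k, df), 0.95, tolerance = 1e-3)
    # monotone non-decreasing in q, bounded in [0, 1]
    v <- studentized_range_cdf(qs, k, df)
    expect_true(all(diff(v) >= 0))
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_equal(studentized_range_cdf(0, 3, 12), 0)
  expect_equal(studentized_range_cdf(3.773, 3, 12), 0.95, tolerance = 1e-3)
})

test_that("k = 2 studentized range reduces to the two-sided t-test", {
  for (df in c(2, 6, 12)) for (q in c(1, 2.5, 4)) {
    p_sr <- 1 - studentized_range_cdf(q, 2, df)
    p_t <- 2 * stats::pt(-q / sqrt(2), df)
    expect_equal(p_sr, p_t, tolerance = 1e-6)
  }
  tk <- tukey_hsd(list(a = c(0, 1), b = c(2, 3)))
  expect_equal(tk$q, 4)
  expect_equal(tk$p, 2 * stats::pt(-2 * sqrt(2), 2), tolerance = 1e-6)
})

test_that("Tukey HSD reproduces the iACS-vs-5xFAD hippocampal Ki67 p-value", {
  s <- subset(neurogenesis_summaries(),
              region == "hippocampus" & marker == "Ki67")
  tk <- tukey_hsd(s)
  p <- tk$p[tk$group1 == "5xFAD" & tk$group2 == "5xFAD+iACS"]
  expect_equal(p, 0.048, tolerance = 0.02 / 0.048) # within +/- 0.02 absolute
  expect_equal(nrow(tk), 3L) # k(k-1)/2 pairs
  # identical groups: q = 0, p = 1
  tk0 <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(tk0$q, 0)
  expect_equal(tk0$p, 1)
  expect_error(tukey_hsd(list(a = 1:3, b = 1:4)), "equal group sizes")
})

test_that("Tukey p never exceeds the Bonferroni-corrected pairwise p", {
  set.seed(3)
  for (rep in 1:10) {
    g <- lapply(1:3, function(i) rnorm(5, i, 2))
    tk <- tukey_hsd(g)
    a <- attr(tk, "anova")
    for (r in seq_len(nrow(tk))) {
      t_stat <- abs(tk$diff[r]) / sqrt(2 * a$ms_within / 5)
      p_unadj <- 2 * stats::pt(-t_stat, a$df_within)
      expect_lte(tk$p[r], min(1, 3 * p_unadj) + 1e-10)
    }
  }
})

test_that("fold changes round to the published one-decimal ratios", {
  fc <- fold_change(812, 224)
  expect_equal(fc$ratio, 3.625)
  expect_equal(fc$ratio_rounded, 3.6)
  expect_equal(fold_change(1510, 777)$ratio_rounded, 1.9)
  expect_equal(fold_change(5, 5)$ratio, 1)
  expect_error(fold_change(1, 0), "> 0")
})

test_that("the reconstructed ANOVA table flags the inconsistent DCX/SVZ cell", {
  pt <- reproduce_published_table()
  expect_equal(nrow(pt$anova), 6L)
  ok <- pt$anova$consistent
  names(ok) <- paste(pt$anova$marker, pt$anova$region)
  expect_true(all(ok[c("Ki67 SVZ", "Ki67 hippocampus", "Nestin SVZ",
                       "Nestin hippocampus", "DCX hippocampus")]))
  expect_false(ok[["DCX SVZ"]])
  # the reconstruction, not the printed value, is reported
  dcx <- pt$anova[pt$anova$marker == "DCX" & pt$anova$region == "SVZ", ]
  expect_equal(dcx$F, 40.7, tolerance = 0.01)
  expect_true(all(pt$anova$df_between == 2 & pt$anova$df_within == 12))
})
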