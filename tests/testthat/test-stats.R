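per_nucleus_stub <- function(cr_by_field, line = "ctrl", repeat_id = 1L) {
  do.call(rbind, lapply(seq_along(cr_by_field), function(i) {
    data.frame(line = line, repeat_id = repeat_id,
               field_id = paste0("f", i),
               contour_ratio = cr_by_field[[i]],
               is_normal = TRUE, elongated = FALSE,
               touches_border = FALSE)
  }))
}

test_that("repeat means weight fields by their nucleus counts", {
  df <- per_nucleus_stub(list(rep(0.8, 10), rep(0.9, 30)))
  s <- summarize_repeat(df, grouping = c("line", "repeat_id"))
  expect_equal(s$mean_contour_ratio, 0.875)
  expect_identical(s$n_nuclei, 40L)
})

test_that("all-normal input gives proportion 1 and zero abnormal classes", {
  df <- per_nucleus_stub(list(rep(0.9, 25)))
  s <- summarize_repeat(df, grouping = c("line", "repeat_id"))
  expect_identical(s$prop_is_normal, 1)
  expect_identical(s$prop_elongated, 0)
})

test_that("border-touching nuclei are excluded from summaries", {
  df <- per_nucleus_stub(list(rep(0.8, 10)))
  df$touches_border[1:5] <- TRUE
  df$contour_ratio[1:5] <- 0.1
  s <- summarize_repeat(df, grouping = c("line", "repeat_id"))
  expect_equal(s$mean_contour_ratio, 0.8)
  expect_identical(s$n_nuclei, 5L)
})

test_that("summaries are invariant to splitting a field into sub-fields", {
  set.seed(33)
  vals <- rnorm(60, 0.85, 0.05)
  one <- per_nucleus_stub(list(vals))
  two <- per_nucleus_stub(list(vals[1:13], vals[14:60]))
  s1 <- summarize_repeat(one, grouping = c("line", "repeat_id"))
  s2 <- summarize_repeat(two, grouping = c("line", "repeat_id"))
  expect_equal(s1$mean_contour_ratio, s2$mean_contour_ratio)
})

test_that("degenerate separation: near-zero SD gives p ~ 0 everywhere", {
  lines <- paste0("L", 1:5)
  s <- data.frame(line = rep(lines, each = 3L),
                  repeat_id = rep(1:3, 5L),
                  mean_contour_ratio = rep(c(0.9, 0.8, 0.7, 0.6, 0.5),
                                           each = 3L) +
                    rep(c(-1, 0, 1) * 1e-9, 5L))
  cmp <- compare_groups(s, "mean_contour_ratio", design = "one_way")
  expect_lt(cmp$p_overall, 1e-12)
  expect_true(all(cmp$posthoc$p_adj < 1e-6))
  expect_true(all(cmp$posthoc$significant))
})

test_that("one-way Tukey p matches the hand-computed studentized range", {
  set.seed(5)
  s <- data.frame(line = rep(c("a", "b", "c"), each = 3L),
                  repeat_id = rep(1:3, 3L),
                  y = rnorm(9, rep(c(0.9, 0.85, 0.7), each = 3L), 0.03))
  cmp <- compare_groups(s, "y", design = "one_way")
  fit <- aov(y ~ line, data = s)
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  means <- tapply(s$y, s$line, mean)
  q <- abs(means["b"] - means["a"]) / sqrt(mse / 3)
  p_manual <- ptukey(q, nmeans = 3, df = 6, lower.tail = FALSE)
  row <- cmp$posthoc[cmp$posthoc$group1 == "b" & cmp$posthoc$group2 == "a", ]
  expect_equal(row$p_adj, unname(p_manual))
  # and agrees with base R's TukeyHSD
  thsd <- TukeyHSD(fit)$line
  expect_equal(sort(cmp$posthoc$p_adj), sort(unname(thsd[, "p adj"])),
               tolerance = 1e-8)
})

test_that("Sidak within-line contrasts match the explicit formula", {
  set.seed(8)
  gm <- expand.grid(line = c("ctrl", "mut"),
                    condition = c("monolayer", "construct3d"))
  gm$mean <- c(0.9, 0.8, 0.88, 0.6)
  s <- simulate_repeat_summaries(gm, sd = 0.02, n_repeats = 3L, metric = "y")
  cmp <- compare_groups(s, "y", design = "two_way")
  sid <- cmp$posthoc[cmp$posthoc$method == "sidak", ]
  fit <- aov(y ~ line * condition, data = transform(
    s, line = factor(line), condition = factor(condition)))
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  dfe <- summary(fit)[[1]]["Residuals", "Df"]
  a <- s$y[s$line == "mut" & s$condition == "monolayer"]
  b <- s$y[s$line == "mut" & s$condition == "construct3d"]
  tt <- (mean(b) - mean(a)) / sqrt(mse * (2 / 3))
  p_manual <- 1 - (1 - 2 * pt(-abs(tt), dfe))^2
  expect_equal(sid$p_adj[sid$within == "mut"], p_manual)
})

test_that("two-way designs demand complete cells and both conditions", {
  s <- data.frame(line = rep(c("a", "b"), each = 4L),
                  condition = rep(c("monolayer", "construct3d"), 4L),
                  repeat_id = rep(1:2, each = 2L), y = rnorm(8))
  missing_cell <- s[!(s$line == "b" & s$condition == "construct3d"), ]
  expect_error(compare_groups(missing_cell, "y", design = "two_way"),
               "empty design cell: line 'b'")
  one_cond <- s[s$condition == "monolayer", ]
  expect_error(compare_groups(one_cond, "y", design = "two_way"),
               "both conditions")
  expect_error(compare_groups(s[1:2, ], "y", design = "one_way"),
               "at least 2")
})

test_that("null p-values are uniform (repeat-level one-way design)", {
  set.seed(1234)
  ps <- replicate(400, {
    s <- data.frame(line = rep(c("a", "b", "c"), each = 3L),
                    repeat_id = rep(1:3, 3L), y = rnorm(9, 0.85, 0.03))
    compare_groups(s, "y", design = "one_way")$p_overall
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the design detects a 0.08 contour-ratio shift at n = 3", {
  set.seed(99)
  hits <- replicate(300, {
    s <- data.frame(line = rep(c("ctrl", "mut"), each = 3L),
                    repeat_id = rep(1:3, 2L),
                    y = rnorm(6, rep(c(0.84, 0.76), each = 3L), 0.02))
    compare_groups(s, "y", design = "one_way")$p_overall < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("condition_contrast flags exactly the affected lines", {
  set.seed(17)
  gm <- expand.grid(line = c("ctrl", "K32del", "R249W", "L35P"),
                    condition = c("monolayer", "construct3d"))
  gm$mean <- 10
  gm$mean[gm$condition == "construct3d" &
            gm$line %in% c("K32del", "L35P")] <- 45
  s <- simulate_repeat_summaries(gm, sd = 8, metric = "prop_elongated")
  cc <- condition_contrast(s, "prop_elongated")
  sig <- cc$posthoc$within[cc$posthoc$significant]
  expect_setequal(sig, c("K32del", "L35P"))
})

test_that("two_way_repeated blocks on the repeat factor", {
  set.seed(3)
  gm <- expand.grid(line = c("a", "b"), condition = c("monolayer",
                                                      "construct3d"))
  gm$mean <- c(0.9, 0.8, 0.9, 0.65)
  s <- simulate_repeat_summaries(gm, sd = 0.02, metric = "y")
  cmp <- compare_groups(s, "y", design = "two_way_repeated")
  expect_s3_class(cmp, "group_comparison")
  expect_true("repeat_id" %in% trimws(rownames(cmp$anova)))
  expect_true(any(cmp$posthoc$method == "sidak"))
})

test_that("render_report writes parseable artefacts in all regimes", {
  out <- withr::local_tempdir()
  # empty input
  paths <- render_report(data.frame(), NULL, list(), file.path(out, "empty"))
  expect_true(file.exists(file.path(out, "empty", "stats.json")))
  expect_silent(jsonlite::fromJSON(file.path(out, "empty", "stats.json")))

  # single group: no post-hoc section
  df <- per_nucleus_stub(list(rnorm(20, 0.85, 0.03)))
  s <- summarize_repeat(df, grouping = c("line", "repeat_id"))
  paths <- render_report(df, s, list(), file.path(out, "single"))
  ctr <- read.csv(file.path(out, "single", "contrasts.csv"))
  expect_identical(nrow(ctr), 0L)
  expect_true(file.exists(file.path(out, "single",
                                    "boxplot_contour_ratio.svg")))

  # full battery: comparisons present and serialized
  set.seed(2)
  s3 <- data.frame(line = rep(c("a", "b", "c"), each = 3L),
                   repeat_id = rep(1:3, 3L),
                   mean_contour_ratio = rnorm(9, 0.8, 0.05))
  cmp <- compare_groups(s3, "mean_contour_ratio", design = "one_way")
  df3 <- data.frame(line = rep(c("a", "b", "c"), each = 30L),
                    contour_ratio = rnorm(90, 0.8, 0.05))
  paths <- render_report(df3, s3, list(cr = cmp), file.path(out, "full"))
  st <- jsonlite::fromJSON(file.path(out, "full", "stats.json"))
  expect_identical(st$n_nuclei, 90L)
  ctr <- read.csv(file.path(out, "full", "contrasts.csv"))
  expect_identical(nrow(ctr), 3L)
})
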