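## Aggregation and inference design: nucleus-level tables are averaged per
## experimental repeat (passage), and all inference runs on the repeat
## means (n = repeats, never n = nuclei). Between-line contrasts use
## Tukey's HSD; within-line (condition or compartment) contrasts use
## Sidak-adjusted t contrasts, both on the ANOVA residual mean square.

PROPORTION_LABELS <- c("jellybean", "severely_deformed", "blebs", "strings",
                       "elongated", "is_normal", "has_honeycomb", "has_foci",
                       "has_capping", "has_emerin_foci", "in_myotube")

#' Summarize a per-nucleus table into repeat-level means
#'
#' Means are taken over all (non-border) nuclei of a repeat, i.e. fields
#' are implicitly weighted by the number of nuclei they contribute, and
#' proportions are fractions of nuclei carrying each label. A nucleus with
#' several shape labels contributes to each of them, so shape-label
#' proportions can sum to more than 1 while `is_normal` plus
#' "any abnormality" is exactly 1.
#'
#' @param per_nucleus data frame with one row per nucleus. Recognized
#'   grouping columns: `line`, `condition`, `repeat_id` (those present are
#'   used); metric columns `contour_ratio`, `major_axis_um`,
#'   `peripheral_ratio`, `peripheral_ratio_b1`; logical label columns among
#'   `jellybean`, `severely_deformed`, `blebs`, `strings`, `elongated`,
#'   `is_normal`, `has_honeycomb`, `has_foci`, `has_capping`,
#'   `has_emerin_foci`, `in_myotube`. `touches_border` rows are excluded.
#' @param grouping character vector of grouping columns; defaults to the
#'   intersection of `c("line", "condition", "repeat_id")` with the table.
#' @return data frame of class `repeat_summary`: grouping columns,
#'   `n_nuclei`, `mean_<metric>` and `prop_<label>` columns. Groups with
#'   zero nuclei are dropped with a warning.
#' @export
summarize_repeat <- function(per_nucleus,
                             grouping = intersect(c("line", "condition",
                                                    "repeat_id"),
                                                  names(per_nucleus))) {
  stopifnot(is.data.frame(per_nucleus), length(grouping) >= 1L,
            all(grouping %in% names(per_nucleus)))
  df <- per_nucleus
  if ("touches_border" %in% names(df)) {
    n_border <- sum(df$touches_border, na.rm = TRUE)
    df <- df[!isTRUE_vec(df$touches_border), , drop = FALSE]
    if (n_border > 0 && nrow(df) == 0L)
      warning("all nuclei touch the field border; empty summary")
  }
  metrics <- intersect(c("contour_ratio", "major_axis_um",
                         "peripheral_ratio", "peripheral_ratio_b1"),
                       names(df))
  labels <- intersect(PROPORTION_LABELS, names(df))
  key <- interaction(df[grouping], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(df)), key)
  rows <- lapply(groups, function(ix) {
    g <- df[ix, , drop = FALSE]
    out <- g[1L, grouping, drop = FALSE]
    out$n_nuclei <- nrow(g)
    for (m in metrics)
      out[[paste0("mean_", m)]] <- mean(g[[m]], na.rm = TRUE)
    for (l in labels)
      out[[paste0("prop_", l)]] <- mean(as.logical(g[[l]]), na.rm = TRUE)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("repeat_summary", "data.frame")
  res
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Compare groups of repeat-level means by ANOVA with post-hoc contrasts
#'
#' Inference always runs on repeat-level values. `one_way` fits
#' `value ~ line` with Tukey HSD pairwise contrasts. `two_way` fits
#' `value ~ line * condition` and reports Tukey contrasts between lines
#' within each condition plus Sidak-adjusted within-line condition
#' contrasts. `two_way_repeated` additionally blocks on `repeat_id`
#' (repeats are paired passages).
#'
#' @param summaries a [summarize_repeat()] table (or any data frame with
#'   the needed grouping columns).
#' @param metric name of the column to analyse (e.g.
#'   `"mean_contour_ratio"`, `"prop_elongated"`).
#' @param design one of `"one_way"`, `"two_way"`, `"two_way_repeated"`.
#' @param alpha significance level (default 0.05).
#' @return object of class `group_comparison`: the design, the `anova`
#'   table, and a `posthoc` data frame with columns `contrast`, `group1`,
#'   `group2`, `within`, `estimate`, `p_adj`, `method`, `significant`.
#' @export
compare_groups <- function(summaries, metric,
                           design = c("one_way", "two_way",
                                      "two_way_repeated"),
                           alpha = 0.05) {
  design <- match.arg(design)
  stopifnot(metric %in% names(summaries))
  df <- as.data.frame(summaries)
  df$.y <- df[[metric]]
  if (any(is.na(df$.y))) stop("metric '", metric, "' contains NA values")
  df$line <- factor(df$line)
  if (nlevels(df$line) < 2L) stop("need at least 2 lines to compare")
  if (min(table(df$line)) < 2L) stop("need at least 2 repeats per group")

  if (design == "one_way") {
    fit <- aov(.y ~ line, data = df)
    an <- summary(fit)[[1L]]
    mse <- an["Residuals", "Mean Sq"]
    dfe <- an["Residuals", "Df"]
    ph <- tukey_contrasts(df, "line", mse, dfe, within = NA_character_)
  } else {
    if (!"condition" %in% names(df)) stop("two-way designs need a 'condition' column")
    df$condition <- factor(df$condition)
    if (nlevels(df$condition) < 2L)
      stop("two-way designs need both conditions present")
    cells <- table(df$line, df$condition)
    if (any(cells == 0L)) {
      empty <- which(cells == 0L, arr.ind = TRUE)[1L, ]
      stop(sprintf("empty design cell: line '%s' x condition '%s'",
                   rownames(cells)[empty[1L]], colnames(cells)[empty[2L]]))
    }
    fml <- if (design == "two_way_repeated") {
      df$repeat_id <- factor(df$repeat_id)
      .y ~ repeat_id + line * condition
    } else .y ~ line * condition
    fit <- aov(fml, data = df)
    an <- summary(fit)[[1L]]
    mse <- an["Residuals", "Mean Sq"]
    dfe <- an["Residuals", "Df"]
    ph_list <- lapply(levels(df$condition), function(cond)
      tukey_contrasts(df[df$condition == cond, , drop = FALSE], "line",
                      mse, dfe, within = cond))
    ph_sidak <- sidak_condition_contrasts(df, mse, dfe)
    ph <- rbind(do.call(rbind, ph_list), ph_sidak)
  }
  ph$significant <- ph$p_adj < alpha
  structure(list(design = design, metric = metric, anova = an,
                 p_overall = an[1L, "Pr(>F)"], posthoc = ph, alpha = alpha),
            class = "group_comparison")
}

## Tukey-Kramer pairwise contrasts of `fac` group means given the model MSE.
tukey_contrasts <- function(df, fac, mse, dfe, within) {
  means <- tapply(df$.y, df[[fac]], mean)
  ns <- tapply(df$.y, df[[fac]], length)
  lev <- names(means)
  k <- length(lev)
  out <- NULL
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    est <- means[j] - means[i]
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(est) / se
    p <- ptukey(q, nmeans = k, df = dfe, lower.tail = FALSE)
    out <- rbind(out, data.frame(
      contrast = paste(lev[j], "-", lev[i]), group1 = lev[j],
      group2 = lev[i], within = within, estimate = unname(est),
      p_adj = unname(p), method = "tukey", stringsAsFactors = FALSE))
  }
  out
}

## Sidak-adjusted condition contrast within each line (family = lines).
sidak_condition_contrasts <- function(df, mse, dfe) {
  lines <- levels(df$line)
  conds <- levels(df$condition)
  m <- length(lines)
  out <- NULL
  for (ln in lines) {
    a <- df$.y[df$line == ln & df$condition == conds[1L]]
    b <- df$.y[df$line == ln & df$condition == conds[2L]]
    est <- mean(b) - mean(a)
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    p <- 2 * pt(-abs(est / se), df = dfe)
    p_adj <- 1 - (1 - p)^m
    out <- rbind(out, data.frame(
      contrast = paste0(ln, ": ", conds[2L], " - ", conds[1L]),
      group1 = conds[2L], group2 = conds[1L], within = ln,
      estimate = est, p_adj = p_adj, method = "sidak",
      stringsAsFactors = FALSE))
  }
  out
}

#' Within-line condition contrast (2D monolayer vs 3D construct)
#'
#' Convenience wrapper for the headline design: two-way ANOVA
#' (line x condition) with Sidak-adjusted within-line condition contrasts.
#'
#' @inheritParams compare_groups
#' @return a `group_comparison` whose `posthoc` is restricted to the Sidak
#'   within-line contrasts.
#' @export
condition_contrast <- function(summaries, metric, alpha = 0.05) {
  res <- compare_groups(summaries, metric, design = "two_way", alpha = alpha)
  res$posthoc <- res$posthoc[res$posthoc$method == "sidak", , drop = FALSE]
  rownames(res$posthoc) <- NULL
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison (%s) on %s\n", x$design, x$metric))
  cat(sprintf("  overall F p-value: %.4g (alpha %.3g)\n", x$p_overall, x$alpha))
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}

#' Simulate repeat-level summaries for design calibration
#'
#' Generates a `line x condition x repeat` table of normally distributed
#' repeat means around stated group means - the tool used to calibrate
#' type-I error and power of the repeat-level ANOVA design without
#' rendering images.
#'
#' @param group_means data frame with columns `line`, `condition` (optional
#'   for one-way layouts) and `mean`.
#' @param sd between-repeat standard deviation.
#' @param n_repeats repeats per cell.
#' @param metric name for the generated value column.
#' @return data frame with `line`, `condition` (if given), `repeat_id` and
#'   the metric column.
#' @export
simulate_repeat_summaries <- function(group_means, sd, n_repeats = 3L,
                                      metric = "mean_contour_ratio") {
  stopifnot(is.data.frame(group_means), "mean" %in% names(group_means),
            "line" %in% names(group_means), sd >= 0, n_repeats >= 2L)
  reps <- group_means[rep(seq_len(nrow(group_means)), each = n_repeats), ,
                      drop = FALSE]
  reps$repeat_id <- rep(seq_len(n_repeats), times = nrow(group_means))
  reps[[metric]] <- rnorm(nrow(reps), mean = reps$mean, sd = sd)
  reps$mean <- NULL
  rownames(reps) <- NULL
  reps
}

#' Write figures and tables for a set of comparisons
#'
#' Produces `stats.json` (ANOVA tables and post-hoc contrasts),
#' `contrasts.csv`, and one SVG box plot per metric (pooled nuclei with the
#' repeat means overlaid, mean marked with `+`). Deterministic for fixed
#' input.
#'
#' @param per_nucleus per-nucleus table (may be empty).
#' @param summaries repeat summary table (may be NULL).
#' @param comparisons named list of `group_comparison` objects (may be
#'   empty).
#' @param out_dir output directory (created if needed).
#' @param metrics metric columns of `per_nucleus` to draw box plots for.
#' @return invisibly, the paths written.
#' @export
render_report <- function(per_nucleus, summaries, comparisons, out_dir,
                          metrics = intersect(c("contour_ratio",
                                                "major_axis_um",
                                                "peripheral_ratio"),
                                              names(per_nucleus))) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  stats <- list(
    n_nuclei = nrow(per_nucleus),
    comparisons = lapply(comparisons, function(x) list(
      design = x$design, metric = x$metric, alpha = x$alpha,
      p_overall = x$p_overall,
      anova = cbind(term = trimws(rownames(x$anova)),
                    as.data.frame(x$anova, check.names = FALSE)),
      posthoc = x$posthoc)))
  p_json <- file.path(out_dir, "stats.json")
  jsonlite::write_json(stats, p_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  paths <- c(paths, p_json)

  contrasts <- do.call(rbind, lapply(names(comparisons), function(nm) {
    ph <- comparisons[[nm]]$posthoc
    if (is.null(ph) || !nrow(ph)) return(NULL)
    cbind(comparison = nm, metric = comparisons[[nm]]$metric, ph)
  }))
  p_csv <- file.path(out_dir, "contrasts.csv")
  if (is.null(contrasts))
    contrasts <- data.frame(comparison = character(0), metric = character(0),
                            contrast = character(0), group1 = character(0),
                            group2 = character(0), within = character(0),
                            estimate = numeric(0), p_adj = numeric(0),
                            method = character(0), significant = logical(0))
  write.csv(contrasts, p_csv, row.names = FALSE)
  paths <- c(paths, p_csv)

  if (nrow(per_nucleus) > 0L && "line" %in% names(per_nucleus)) {
    for (m in metrics) {
      p_fig <- file.path(out_dir, paste0("boxplot_", m, ".svg"))
      grDevices::svg(p_fig, width = 7, height = 5)
      grp <- if ("condition" %in% names(per_nucleus))
        interaction(per_nucleus$line, per_nucleus$condition, sep = " / ")
      else factor(per_nucleus$line)
      graphics::boxplot(per_nucleus[[m]] ~ grp, range = 0,
                        xlab = "", ylab = m, las = 2, cex.axis = 0.7)
      mu <- tapply(per_nucleus[[m]], grp, mean, na.rm = TRUE)
      graphics::points(seq_along(mu), mu, pch = 3, cex = 1.2)
      grDevices::dev.off()
      paths <- c(paths, p_fig)
    }
  }
  invisible(paths)
}
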