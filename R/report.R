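# Cohort-level report tables: group summaries (median/IQR), pairwise
# rank-sum tests, per-group Spearman correlations against the emulated
# macrophotography area, and least-squares fits. Shapes follow the study
# report: one summary row per power x time group; pairwise contrasts are
# 30-vs-60 W within each time and 2-vs-4 s within each power.

group_key <- function(power_w, duration_s) sprintf("%gW_%gs", power_w, duration_s)

#' Per-group median/IQR summary of thermal spread
#'
#' @param manifest Cohort manifest data.frame (needs `power_w`,
#'   `duration_s`, `dropped`, and the `value_col`).
#' @param value_col Column summarised (default `"spread_area_mm2"`).
#' @return data.frame: `power_w`, `duration_s`, `n`, `median`, `iqr`, `q1`,
#'   `q3`. Rejected (dropped) sessions are excluded.
#' @export
group_summary_table <- function(manifest, value_col = "spread_area_mm2") {
  df <- manifest[!manifest$dropped, , drop = FALSE]
  groups <- unique(df[, c("power_w", "duration_s")])
  groups <- groups[order(groups$power_w, groups$duration_s), , drop = FALSE]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    v <- df[[value_col]][df$power_w == g$power_w & df$duration_s == g$duration_s]
    s <- median_iqr(v)
    data.frame(power_w = g$power_w, duration_s = g$duration_s, n = s$n,
               median = s$median, iqr = s$iqr, q1 = s$q1, q3 = s$q3)
  })
  do.call(rbind, rows)
}

#' Pairwise rank-sum tests between setting groups
#'
#' Runs the study's subgroup contrasts: 30-vs-60 W within each application
#' time, and 2-vs-4 s within each power setting.
#'
#' @inheritParams group_summary_table
#' @return data.frame: `contrast`, `fixed`, `n1`, `n2`, `statistic`,
#'   `p_value`, `method`.
#' @export
pairwise_test_table <- function(manifest, value_col = "spread_area_mm2") {
  df <- manifest[!manifest$dropped, , drop = FALSE]
  val <- function(p, s) df[[value_col]][df$power_w == p & df$duration_s == s]
  rows <- list()
  add <- function(contrast, fixed, x, y) {
    if (length(x) < 1L || length(y) < 1L) return()
    t <- wilcoxon_ranksum(x, y)
    rows[[length(rows) + 1L]] <<- data.frame(
      contrast = contrast, fixed = fixed, n1 = t$n1, n2 = t$n2,
      statistic = t$statistic, p_value = t$p_value, method = t$method)
  }
  for (s in sort(unique(df$duration_s))) {
    add("30W_vs_60W", sprintf("%gs", s), val(30, s), val(60, s))
  }
  for (p in sort(unique(df$power_w))) {
    add("2s_vs_4s", sprintf("%gW", p), val(p, 2), val(p, 4))
  }
  do.call(rbind, rows)
}

#' Per-group Spearman correlation between two area measures
#'
#' @inheritParams group_summary_table
#' @param x_col,y_col Columns correlated (default thermal spread vs the
#'   emulated macrophotography area).
#' @return data.frame: `power_w`, `duration_s`, `n`, `spearman_r`. Groups
#'   with fewer than 3 usable pairs are reported with `NA`.
#' @export
correlation_table <- function(manifest, x_col = "spread_area_mm2",
                              y_col = "macro_area_mm2") {
  df <- manifest[!manifest$dropped, , drop = FALSE]
  groups <- unique(df[, c("power_w", "duration_s")])
  groups <- groups[order(groups$power_w, groups$duration_s), , drop = FALSE]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sel <- df$power_w == g$power_w & df$duration_s == g$duration_s
    x <- df[[x_col]][sel]; y <- df[[y_col]][sel]
    r <- if (length(x) >= 3L && length(unique(x)) > 1L && length(unique(y)) > 1L) {
      spearman_cor(x, y)$r
    } else NA_real_
    data.frame(power_w = g$power_w, duration_s = g$duration_s,
               n = length(x), spearman_r = r)
  })
  do.call(rbind, rows)
}

#' Per-group and overall regression fits between two area measures
#'
#' @inheritParams correlation_table
#' @return data.frame: `scope`, `n`, `slope`, `intercept`, `r_squared`.
#' @export
regression_table <- function(manifest, x_col = "spread_area_mm2",
                             y_col = "macro_area_mm2") {
  df <- manifest[!manifest$dropped, , drop = FALSE]
  rows <- list()
  add <- function(scope, x, y) {
    if (length(x) < 2L || length(unique(x)) == 1L) return()
    f <- linear_fit(x, y)
    rows[[length(rows) + 1L]] <<- data.frame(
      scope = scope, n = length(x), slope = f$slope,
      intercept = f$intercept, r_squared = f$r_squared)
  }
  add("all", df[[x_col]], df[[y_col]])
  groups <- unique(df[, c("power_w", "duration_s")])
  groups <- groups[order(groups$power_w, groups$duration_s), , drop = FALSE]
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    sel <- df$power_w == g$power_w & df$duration_s == g$duration_s
    add(group_key(g$power_w, g$duration_s), df[[x_col]][sel], df[[y_col]][sel])
  }
  do.call(rbind, rows)
}
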