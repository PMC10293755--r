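# Nonparametric statistical layer: median/IQR summaries, the two-sided
# independent-samples Wilcoxon rank-sum (Mann-Whitney) test with exact
# small-sample p-values, Spearman rank correlation, and ordinary
# least-squares fits. Implemented directly (not delegated to stats::*.test)
# so small-sample and tie behaviour is explicit and testable.
#
# Conventions, stated once:
# * Quantiles: linear interpolation between order statistics at position
#   p * (n - 1) (the common scientific-software default); IQR = Q3 - Q1.
# * Ties: mid-ranks everywhere; the exact test permutes the actual
#   mid-ranks.
# * Two-sided exact p: probability, over all C(n1+n2, n1) equally likely
#   group assignments, of a rank sum at least as far from its permutation
#   mean as the observed one.

quantile_lin <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  pos <- p * (n - 1)
  lo <- floor(pos) + 1
  hi <- ceiling(pos) + 1
  x[lo] + (pos - floor(pos)) * (x[hi] - x[lo])
}

#' Median and interquartile range
#'
#' @param values Numeric vector (n >= 1, finite).
#' @return List: `n`, `median`, `q1`, `q3`, `iqr` (= q3 - q1), using linear
#'   interpolation between order statistics (position `p * (n - 1)`).
#' @export
#' @examples
#' median_iqr(c(1, 2, 3, 4)) # median 2.5, iqr 1.5
median_iqr <- function(values) {
  if (length(values) == 0L) stop_value("median_iqr needs at least one value")
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    stop_value("values must be finite numerics")
  }
  q1 <- quantile_lin(values, 0.25)
  q3 <- quantile_lin(values, 0.75)
  list(n = length(values), median = quantile_lin(values, 0.5),
       q1 = q1, q3 = q3, iqr = q3 - q1)
}

midranks <- function(x) rank(x, ties.method = "average")

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p-values by complete enumeration of all group assignments of the
#' combined mid-ranks when `n1 + n2 <= 20` (mode `"auto"`), otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction.
#'
#' @param x,y Independent samples (each n >= 1).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return List of class `ranksum_test`: `statistic` (rank sum of `x`),
#'   `p_value`, `method`, `n1`, `n2`, `degenerate` (TRUE when all values
#'   across both samples are identical, in which case p = 1).
#' @export
#' @examples
#' wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))$p_value # 0.1 exactly
wilcoxon_ranksum <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) < 1L || length(y) < 1L) stop_value("both samples need n >= 1")
  if (anyNA(c(x, y)) || any(!is.finite(c(x, y)))) stop_value("samples must be finite")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- midranks(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    return(structure(list(statistic = w, p_value = 1, method = "degenerate",
                          n1 = n1, n2 = n2, degenerate = TRUE),
                     class = "ranksum_test"))
  }
  if (mode == "auto") mode <- if (n <= 20L) "exact" else "approx"
  if (mode == "exact") {
    if (n > 22L) stop_value("exact enumeration limited to n1 + n2 <= 22; use approx")
    sums <- utils::combn(r, n1, FUN = sum)
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal_approx"
  }
  structure(list(statistic = w, p_value = p, method = method,
                 n1 = n1, n2 = n2, degenerate = FALSE),
            class = "ranksum_test")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (so ties are handled); equals
#' `1 - 6 * sum(d^2) / (n (n^2 - 1))` when there are no ties.
#'
#' @param x,y Paired samples, equal length, n >= 3.
#' @return List of class `correlation_result`: `r`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop_value("x and y must have equal length")
  if (length(x) < 3L) stop_value("Spearman correlation needs n >= 3")
  if (anyNA(c(x, y)) || any(!is.finite(c(x, y)))) stop_value("samples must be finite")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop_value("undefined correlation: a variable is constant")
  }
  rx <- midranks(x); ry <- midranks(y)
  rx <- rx - mean(rx); ry <- ry - mean(ry)
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  structure(list(r = r, n = length(x)), class = "correlation_result")
}

#' Ordinary least-squares line fit
#'
#' @param x,y Paired samples, n >= 2; `x` must not be constant.
#' @return List of class `regression_fit`: `slope`, `intercept`,
#'   `r_squared` (`1 - SSres/SStot`; defined as 0 when `y` is constant).
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop_value("linear_fit needs paired samples of length >= 2")
  }
  if (anyNA(c(x, y)) || any(!is.finite(c(x, y)))) stop_value("samples must be finite")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop_value("singular fit: x is constant")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) 0 else 1 - sum((y - (intercept + slope * x))^2) / sstot
  structure(list(slope = slope, intercept = intercept,
                 r_squared = max(0, min(1, r2))),
            class = "regression_fit")
}
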