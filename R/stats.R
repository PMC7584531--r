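#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability ("minimum-likelihood") two-sided test: the p-value is the
#' sum, over all tables with the observed margins, of hypergeometric point
#' probabilities no larger than that of the observed table, with a relative
#' tolerance of 1e-7 for floating-point ties. Computed on the raw counts;
#' zero-cell corrections never apply to the p-value.
#'
#' @param a,b,c,d Cell counts: `a` exposed cases, `b` unexposed cases, `c`
#'   exposed controls, `d` unexposed controls.
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(5, 42, 0, 42)   # 0.0574...
fisher_exact_2x2 <- function(a, b, c, d) {
  .check_cells(a, b, c, d)
  n1 <- a + b
  n2 <- c + d
  m <- a + c
  if (n1 + n2 == 0) stop("at least one margin must be positive")
  if (m == 0 || m == n1 + n2 || n1 == 0 || n2 == 0) return(1)
  x <- max(0, m - n2):min(m, n1)
  px <- stats::dhyper(x, n1, n2, m)
  p0 <- stats::dhyper(a, n1, n2, m)
  min(1, sum(px[px <= p0 * (1 + 1e-7)]))
}

.check_cells <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  invisible(cells)
}

#' Odds ratio with Haldane-Anscombe zero-cell correction
#'
#' `OR = (a*d) / (b*c)` on the raw cells; if any cell is zero, 0.5 is first
#' added to all four cells (Haldane-Anscombe). The correction affects the odds
#' ratio and its confidence interval only, never the Fisher p-value.
#'
#' @inheritParams fisher_exact_2x2
#' @return List with `odds_ratio` and `haldane_applied`.
#' @export
#' @examples
#' odds_ratio_2x2(5, 42, 0, 42)   # 11.0, corrected
odds_ratio_2x2 <- function(a, b, c, d) {
  .check_cells(a, b, c, d)
  haldane <- any(c(a, b, c, d) == 0)
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  list(odds_ratio = (a * d) / (b * c), haldane_applied = haldane)
}

#' Woolf (logit) confidence interval for an odds ratio
#'
#' `exp(ln OR +/- z * SE)` with `SE = sqrt(1/a + 1/b + 1/c + 1/d)` over the
#' cells, Haldane-corrected exactly as in [odds_ratio_2x2()] when any raw cell
#' is zero. `z` is the exact standard-normal quantile for the level
#' (1.959964 at 95%).
#'
#' @inheritParams fisher_exact_2x2
#' @param level Confidence level in (0, 1). Default 0.95.
#' @return List with `ci_low`, `ci_high`, `haldane_applied`.
#' @export
woolf_ci <- function(a, b, c, d, level = 0.95) {
  .check_cells(a, b, c, d)
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("level must lie in (0, 1)")
  }
  haldane <- any(c(a, b, c, d) == 0)
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       haldane_applied = haldane)
}

#' Full association result for a 2x2 table
#'
#' Combines the two-sided Fisher exact p-value (raw cells), Haldane-corrected
#' odds ratio, and Woolf confidence interval into one row.
#'
#' @inheritParams woolf_ci
#' @return One-row tibble: `a`, `b`, `c`, `d`, `p_value`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `haldane_applied`.
#' @export
association_2x2 <- function(a, b, c, d, level = 0.95) {
  p <- fisher_exact_2x2(a, b, c, d)
  or <- odds_ratio_2x2(a, b, c, d)
  ci <- woolf_ci(a, b, c, d, level)
  tibble::tibble(
    a = a, b = b, c = c, d = d,
    p_value = p,
    odds_ratio = or$odds_ratio,
    ci_low = ci$ci_low, ci_high = ci$ci_high,
    haldane_applied = or$haldane_applied
  )
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance (default) or Welch two-sample t-test computed from group
#' means, standard deviations and sizes; two-sided p. With both standard
#' deviations zero and equal means the result is t = 0, p = 1 by convention.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param var_equal Pooled variance if `TRUE` (default), Welch otherwise.
#' @return List with `t_statistic`, `df`, `p_value`.
#' @export
#' @examples
#' pooled_t_test(1.970, 0.901, 47, 1.762, 0.961, 42)$p_value  # ~0.295
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = TRUE) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  diff <- mean1 - mean2
  if (sd1 == 0 && sd2 == 0) {
    if (diff == 0) {
      return(list(t_statistic = 0, df = n1 + n2 - 2, p_value = 1))
    }
    return(list(t_statistic = sign(diff) * Inf, df = n1 + n2 - 2, p_value = 0))
  }
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t_stat <- diff / se
  list(t_statistic = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df))
}

#' Reconstruct a count from a printed percentage
#'
#' `k = round(pct * n / 100)` (half-up), with a consistency check that the
#' reconstructed count re-rounds to the printed percent; an inconsistency
#' raises a warning, not an error. Published case-control tables often print
#' only group sizes and frequencies; this recovers the underlying 2x2 cells.
#'
#' @param pct Printed percent in [0, 100].
#' @param n Group size.
#' @return Integer count with attribute `consistent` (logical).
#' @export
#' @examples
#' counts_from_percent(11, 47)  # 5
counts_from_percent <- function(pct, n) {
  if (any(pct < 0 | pct > 100)) stop("percent must lie in [0, 100]")
  if (any(n <= 0)) stop("group size must be positive")
  k <- as.integer(floor(pct * n / 100 + 0.5))
  back <- floor(100 * k / n + 0.5)
  consistent <- back == round(pct)
  if (any(!consistent)) {
    warning(sprintf("count %d/%d re-rounds to %d%%, printed %g%%",
                    k[!consistent][1], n[!consistent][1],
                    back[!consistent][1], pct[!consistent][1]))
  }
  attr(k, "consistent") <- consistent
  k
}
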