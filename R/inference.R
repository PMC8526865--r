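# Nonparametric tests, effect sizes and confidence intervals.

#' Two-sided Wilcoxon signed-rank test with Hodges-Lehmann interval
#'
#' Tests the location of `values` against `mu`. The exact signed-rank
#' distribution is used when fewer than 50 nonzero deviations remain and
#' there are no zeros or ties; otherwise the normal approximation with
#' continuity and tie correction applies (zeros are dropped before ranking,
#' ties get midranks). The confidence interval inverts the test over Walsh
#' averages; the point estimate is the pseudomedian (median of Walsh
#' averages).
#'
#' @param values Numeric sample.
#' @param mu Null location (default 0).
#' @param conf Confidence level (default 0.95).
#' @param ci Compute the interval and pseudomedian (default TRUE; disable
#'   for speed in simulations).
#' @return List of class `lwl_wilcoxon`: `V`, `p`, `method` (`EXACT` or
#'   `NORMAL_APPROX`), `ci_low`, `ci_high`, `pseudomedian`, `n_used`.
#' @export
wilcoxon_signed_rank <- function(values, mu = 0, conf = 0.95, ci = TRUE) {
  d <- values[!is.na(values)] - mu
  nonzero <- d[d != 0]
  if (!length(nonzero)) {
    stop("degenerate data: all deviations from mu are zero", call. = FALSE)
  }
  exact <- length(nonzero) < 50 && !any(d == 0) &&
    !any(duplicated(abs(nonzero)))
  res <- suppressWarnings(
    stats::wilcox.test(values, mu = mu, conf.int = ci, conf.level = conf,
                       exact = exact, correct = TRUE)
  )
  structure(list(
    V = unname(res$statistic),
    p = res$p.value,
    method = if (exact) "EXACT" else "NORMAL_APPROX",
    ci_low = if (ci) res$conf.int[1] else NA_real_,
    ci_high = if (ci) res$conf.int[2] else NA_real_,
    pseudomedian = if (ci) unname(res$estimate) else NA_real_,
    n_used = length(nonzero),
    conf = conf
  ), class = "lwl_wilcoxon")
}

#' @export
print.lwl_wilcoxon <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): V = %.2f, %d%% CI [%.3f, %.3f], p = %.3g (n = %d)\n",
              x$method, x$V, round(100 * x$conf), x$ci_low, x$ci_high, x$p, x$n_used))
  invisible(x)
}

#' One-sample Cohen's d
#'
#' `(mean(values) - mu) / sd(values)` with the n-1 standard deviation.
#'
#' @param values Numeric sample (n >= 2, positive variance).
#' @param mu Null location.
#' @return Effect size d.
#' @export
cohens_d_one_sample <- function(values, mu = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least two values", call. = FALSE)
  s <- sd(values)
  if (s == 0) stop("zero variance", call. = FALSE)
  (mean(values) - mu) / s
}

#' Kruskal-Wallis rank-sum test
#'
#' Midrank-based H statistic with tie correction; p from the chi-squared
#' distribution with `k - 1` degrees of freedom.
#'
#' @param groups List of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @return List of class `lwl_kruskal`: `H`, `df`, `p`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop("empty group in Kruskal-Wallis input", call. = FALSE)
  }
  res <- stats::kruskal.test(groups)
  structure(list(H = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value, n = sum(lengths(groups))),
            class = "lwl_kruskal")
}

#' @export
print.lwl_kruskal <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi-squared(%d, N = %d) = %.2f, p = %.3g\n",
              x$df, x$n, x$H, x$p))
  invisible(x)
}

#' Pearson correlation test
#'
#' Standard Pearson r with p-value from `t = r * sqrt(df / (1 - r^2))`,
#' `df = n - 2`; one-sided alternatives supported.
#'
#' @param x,y Numeric vectors (n >= 3, positive variances).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return List of class `lwl_correlation`: `r`, `df`, `p`, `alternative`,
#'   `n`.
#' @export
pearson_r <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least three complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance", call. = FALSE)
  res <- stats::cor.test(x, y, method = "pearson", alternative = alternative)
  structure(list(r = unname(res$estimate), df = unname(res$parameter),
                 p = res$p.value, alternative = alternative, n = length(x)),
            class = "lwl_correlation")
}

#' @export
print.lwl_correlation <- function(x, ...) {
  cat(sprintf("Pearson correlation (%s): r(%d) = %.3f, p = %.3g\n",
              x$alternative, x$df, x$r, x$p))
  invisible(x)
}
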