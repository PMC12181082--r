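#' Paired Wilcoxon signed-rank test
#'
#' Differences `a - b` are formed pairwise; zero differences are dropped
#' (Wilcoxon's rule, not Pratt's). Absolute differences are ranked with
#' midranks for ties. The p-value is exact — equivalent to enumerating all
#' sign assignments — when no more than 25 nonzero tie-free differences
#' remain; otherwise the normal approximation with tie correction and
#' continuity correction is used. Computation is delegated to
#' [stats::wilcox.test()] with the branch chosen explicitly.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param alternative `"two_sided"`, `"greater"` (a tends to exceed b) or
#'   `"less"`.
#' @return object of class `wilcoxon_result`: `statistic_w` (sum of ranks of
#'   positive differences), `p_value`, `n_effective`, `alternative`,
#'   `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' wilcoxon_signed_rank(c(2, 4, 7, 11, 16), c(1, 2, 3, 4, 5),
#'                      alternative = "greater")$p_value  # 1/32
#' @export
wilcoxon_signed_rank <- function(a, b,
                                 alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 1L) stop("need at least one pair")
  d <- a - b
  d <- d[d != 0]
  n_eff <- length(d)
  if (n_eff == 0L) stop("all differences are zero: test undefined")
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- n_eff <= 25L && !ties
  alt <- switch(alternative, two_sided = "two.sided", greater = "greater",
                less = "less")
  wt <- suppressWarnings(
    wilcox.test(d, alternative = alt, mu = 0, exact = exact, correct = TRUE))
  structure(list(statistic_w = unname(wt$statistic), p_value = wt$p.value,
                 n_effective = n_eff, alternative = alternative,
                 method = if (exact) "exact" else "normal_approx"),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_result> W = %g, p = %.4g (%s, %s, n_eff = %d)\n",
              x$statistic_w, x$p_value, x$alternative, x$method, x$n_effective))
  invisible(x)
}

#' Descriptive summary of a numeric sample
#'
#' Mean, SD (n-1 denominator), median, IQR and a percentile range, with
#' percentiles computed by linear interpolation between order statistics
#' (`stats::quantile` type 7) — the same convention used for surface
#' deviation maps. SD is `NA` (flagged) for a single value.
#'
#' @param values numeric vector, length >= 1.
#' @param range_levels two probabilities for the percentile range; default
#'   `c(0.1, 0.9)`.
#' @return list: `n`, `mean`, `sd`, `sd_defined`, `median`, `iqr`,
#'   `range_levels`, `range_low`, `range_high`.
#' @export
summarize_values <- function(values, range_levels = c(0.1, 0.9)) {
  if (length(values) < 1L) stop("cannot summarise an empty sample")
  if (any(!is.finite(values))) stop("values must be finite")
  q <- quantile(values, probs = range_levels, type = 7, names = FALSE)
  list(n = length(values),
       mean = mean(values),
       sd = if (length(values) >= 2L) sd(values) else NA_real_,
       sd_defined = length(values) >= 2L,
       median = median(values),
       iqr = diff(quantile(values, c(0.25, 0.75), type = 7, names = FALSE)),
       range_levels = range_levels,
       range_low = q[1], range_high = q[2])
}
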