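# Shared statistics: Mann-Whitney U, Spearman, hypergeometric overlap,
# notched-boxplot summaries, and binning.

#' Map p-values to significance stars
#'
#' The convention used throughout the figures: `****` p < 0.0001, `***`
#' p < 0.001, `**` p < 0.01, `*` p < 0.05, otherwise `n.s.`.
#' @param p numeric vector of p-values.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "n.s."), right = FALSE) |>
    as.character()
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration when the combined sample size is at most 12 and there
#' are no ties; otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact_max combined size at or below which the exact test is used.
#' @return list with `median_x`, `median_y`, `U` (for `x`), `p` and `stars`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(median_x = stats::median(x), median_y = stats::median(y),
       U = unname(wt$statistic), p = min(1, wt$p.value),
       stars = significance_stars(min(1, wt$p.value)))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks; p from the t transform with n - 2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p` (`NA` when either rank vector is
#'   constant).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), df = n - 2))
}

#' Hypergeometric overlap test
#'
#' Upper-tail probability P(X >= k) that two gene sets of sizes `na` and
#' `nb` drawn from a universe of size `n_universe` share at least `k`
#' members, computed in log space via [stats::phyper].
#'
#' @param k observed overlap.
#' @param na,nb set sizes.
#' @param n_universe universe size.
#' @export
hypergeometric_overlap <- function(k, na, nb, n_universe) {
  if (k > min(na, nb) || na > n_universe || nb > n_universe || k < 0)
    stop("inconsistent sizes: need k <= min(na, nb) <= N")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, na, n_universe - na, nb,
                    lower.tail = FALSE, log.p = TRUE))
}

#' Notched-boxplot summary
#'
#' Quartiles by type-7 linear interpolation; the notch half-width is
#' 1.58 * IQR / sqrt(n), the conventional ~95% interval around the median
#' (non-overlapping notches indicate roughly 95% confidence that two
#' medians differ).
#'
#' @param values numeric vector, n >= 2.
#' @return list with `median`, `q1`, `q3`, `notch_low`, `notch_high`, `n`.
#' @export
notched_summary <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  half <- 1.58 * (q[3] - q[1]) / sqrt(n)
  list(median = q[2], q1 = q[1], q3 = q[3],
       notch_low = q[2] - half, notch_high = q[2] + half, n = n)
}

#' Assign items to quantile or fixed-size bins
#'
#' `quantile` mode splits the ranked items into `k` near-equal bins (sizes
#' differ by at most one). `fixed_size` mode orders by
#' `order_key` and takes consecutive blocks of `m` items, the remainder
#' going to the last bin. Ties are broken by stable input order.
#'
#' @param values numeric vector to bin.
#' @param mode `"quantile"` or `"fixed_size"`.
#' @param k number of quantile bins.
#' @param m fixed bin size.
#' @param order_key ranking key (defaults to `values`).
#' @return integer vector of bin indices (1-based), in input order.
#' @export
make_bins <- function(values, mode = c("quantile", "fixed_size"),
                      k = 5, m = 100, order_key = values) {
  mode <- match.arg(mode)
  n <- length(values)
  if (!n) stop("values must be non-empty")
  rk <- rank(order_key, ties.method = "first")
  if (mode == "quantile") {
    if (k < 1) stop("k must be >= 1")
    # near-equal bins: sizes differ by at most one
    as.integer(floor((rk - 1) * k / n) + 1)
  } else {
    if (m < 1) stop("m must be >= 1")
    pmin(as.integer(ceiling(rk / m)), as.integer(ceiling(n / m)))
  }
}
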