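#' Wilcoxon signed-rank test with exact small-sample p values
#'
#' Paired signed-rank test. Zero differences are dropped (their count is
#' reported); ranks of the absolute differences use average ranks for
#' ties; the statistic `W` is the sum of ranks of positive differences.
#' For `n <= exact_limit` nonzero differences the two-sided p value is
#' exact over all `2^n` equiprobable sign assignments (computed by dynamic
#' programming over the rank distribution, which is symmetric about
#' `sum(ranks)/2`): `p = P(|W - mu| >= |w_obs - mu|)`. For larger `n` a
#' normal approximation with tie-corrected variance `sum(ranks^2)/4` and a
#' 0.5 continuity correction is used. The method actually applied is
#' recorded in the result.
#'
#' @param x,y paired samples of equal length; with `y = NULL`, `x` is
#'   taken as the differences
#' @param exact_limit largest `n` for which the exact distribution is used
#' @return one-row data frame: `test`, `method`, `n`, `n_zero_dropped`,
#'   `W`, `p_value`, `stars`
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 25L) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    x - y
  }
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero; signed-rank test undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, W)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2)) / 2
    z <- max(abs(W - mu) - 0.5, 0) / sigma
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal-approximation"
  }
  data.frame(test = "wilcoxon-signed-rank", method = method, n = n,
             n_zero_dropped = n_zero, W = W, p_value = p,
             stars = star_annotation(p), stringsAsFactors = FALSE)
}

# Exact two-sided p over all 2^n sign assignments. Ranks are doubled so
# average (half-integer) tie ranks become integers; the distribution of
# the doubled positive-rank sum is built by convolution.
signed_rank_exact_p <- function(ranks, W) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L)   # counts[s + 1] = #assignments with sum s
  counts[1L] <- 1
  for (rk in r2) {
    shifted <- c(numeric(rk), counts[seq_len(total + 1L - rk)])
    counts <- counts + shifted
  }
  s <- 0:total
  dev_obs <- abs(2 * W - total / 2)   # deviation of the doubled statistic
  dev <- abs(s - total / 2)
  sum(counts[dev >= dev_obs - 1e-9]) / 2^length(r2)
}

#' Significance stars for a p value
#'
#' Banding rule: `***` for p <= 0.0009, `**` for p <= 0.009, `*` for
#' p <= 0.05, `ns` otherwise (all bounds inclusive).
#'
#' @param p p value(s) in `[0, 1]`
#' @return character vector of `"ns"`, `"*"`, `"**"`, `"***"`
#' @export
star_annotation <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p values must lie in [0, 1]")
  ifelse(p <= 0.0009, "***",
         ifelse(p <= 0.009, "**",
                ifelse(p <= 0.05, "*", "ns")))
}

#' Tukey boxplot summary
#'
#' Quartiles by linear interpolation (type 7); whiskers extend to the
#' furthest observation within 1.5 IQR of the quartiles; points beyond the
#' whiskers are outliers.
#'
#' @param values numeric vector, length >= 1
#' @return list: `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `n`
#' @export
boxplot_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]), n = length(values))
}

#' Compare two conditions nonparametrically
#'
#' The study applies a signed-rank test to per-cell efficiencies. Cells of
#' two conditions are not naturally paired, so with `test = "signed-rank"`
#' and equal group sizes the samples are paired by rank order (i-th
#' smallest with i-th smallest) before testing; the pairing choice is
#' recorded in the result. `test = "rank-sum"` runs the unpaired
#' Mann-Whitney alternative (recommended for independent cell populations)
#' via [stats::wilcox.test()].
#'
#' @param x,y numeric samples for the two conditions
#' @param labels length-2 character vector of condition labels
#' @param test `"signed-rank"` or `"rank-sum"`
#' @return one-row data frame: `condition_a`, `condition_b`, `test`,
#'   `method`, `pairing`, `n_a`, `n_b`, `W`, `p_value`, `stars`
#' @export
compare_conditions <- function(x, y, labels = c("a", "b"),
                               test = c("signed-rank", "rank-sum")) {
  test <- match.arg(test)
  if (test == "signed-rank") {
    if (length(x) != length(y))
      stop("signed-rank pairing needs equal group sizes; ",
           "use test = \"rank-sum\" for unequal groups")
    res <- wilcoxon_signed_rank(sort(x), sort(y))
    data.frame(condition_a = labels[1L], condition_b = labels[2L],
               test = res$test, method = res$method, pairing = "rank-order",
               n_a = length(x), n_b = length(y), W = res$W,
               p_value = res$p_value, stars = res$stars,
               stringsAsFactors = FALSE)
  } else {
    wt <- stats::wilcox.test(x, y, exact = NULL, correct = TRUE)
    data.frame(condition_a = labels[1L], condition_b = labels[2L],
               test = "wilcoxon-rank-sum", method = wt$method,
               pairing = "none", n_a = length(x), n_b = length(y),
               W = unname(wt$statistic), p_value = wt$p.value,
               stars = star_annotation(wt$p.value),
               stringsAsFactors = FALSE)
  }
}
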