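# paired_stats: relative island values, exact/approximate Wilcoxon
# signed-rank tests, percentile bootstrap CIs, correlations.

#' Relative island value
#'
#' `x_island / (x_island + x_mainland)`: 0.5 under island-mainland equality.
#' Undefined (`NA`, excluded downstream) when both inputs are 0, because such
#' comparisons are uninformative. Vectorised.
#'
#' @param x_island,x_mainland nonnegative finite statistics.
#' @return values in `[0, 1]`, `NA` where both inputs are 0.
#' @export
relative_value <- function(x_island, x_mainland) {
  if (any(x_island < 0, na.rm = TRUE) || any(x_mainland < 0, na.rm = TRUE))
    stop("relative_value: negative input")
  out <- x_island / (x_island + x_mainland)
  out[is.nan(out)] <- NA_real_  # 0/0
  out
}

# exact null distribution of W+ (sum of signed ranks of positives) by
# generating-function DP; mid-ranks doubled so all masses sit on integers.
.signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1L)  # f[w+1] = P(2*W+ == w)
  f[1] <- 1
  for (r in r2) {
    g <- f / 2
    shifted <- c(numeric(r), g[seq_len(total + 1L - r)])
    f <- g + shifted
  }
  f
}

#' Wilcoxon signed-rank test against a centre of symmetry
#'
#' Tests whether `values` are symmetrically distributed about `null_center`
#' (0.5 for relative island values). Zero differences are dropped; tied
#' absolute differences receive mid-ranks. For `m <= exact_max` nonzero
#' differences the null distribution of the signed-rank sum is computed
#' exactly (equivalent to enumerating all `2^m` sign assignments); above that
#' a normal approximation with continuity and tie correction is used.
#'
#' @param values numeric vector (NAs dropped).
#' @param null_center centre of symmetry under the null (default 0.5).
#' @param tail `"less"` (alternative: location below the centre),
#'   `"greater"`, or `"two_sided"`.
#' @param exact_max largest m for which the exact null is used (default 20).
#' @return a list with `p_value`, `statistic` (W+), `m` (nonzero
#'   differences), `exact` (logical), `tail`.
#' @export
wilcoxon_signed_rank <- function(values, null_center = 0.5,
                                 tail = c("two_sided", "less", "greater"),
                                 exact_max = 20L) {
  tail <- match.arg(tail)
  values <- values[!is.na(values)]
  d <- values - null_center
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) stop("wilcoxon_signed_rank: all differences are zero; test undefined")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (m <= exact_max) {
    f <- .signed_rank_null(r)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(f[seq_len(w2 + 1L)])
    p_ge <- sum(f[seq.int(w2 + 1L, length(f))])
    p <- switch(tail,
                less = p_le,
                greater = p_ge,
                two_sided = min(1, 2 * min(p_le, p_ge)))
    exact <- TRUE
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z_le <- (w - mu + 0.5) / sigma
    z_ge <- (w - mu - 0.5) / sigma
    p <- switch(tail,
                less = pnorm(z_le),
                greater = pnorm(z_ge, lower.tail = FALSE),
                two_sided = min(1, 2 * min(pnorm(z_le),
                                           pnorm(z_ge, lower.tail = FALSE))))
    exact <- FALSE
  }
  list(p_value = p, statistic = w, m = m, exact = exact, tail = tail)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the values with replacement `n_boot` times and returns the
#' percentile interval of the resampled means. The point estimate is the
#' plain sample mean. Deterministic given `seed`; the caller's RNG state is
#' preserved.
#'
#' @param values numeric vector, length >= 2 (NAs dropped).
#' @param n_boot number of bootstrap datasets (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed (required for reproducibility).
#' @return list with `mean`, `ci_lower`, `ci_upper`, `n`, `n_boot`, `seed`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 1000L, level = 0.95, seed) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("bootstrap requires at least 2 values")
  if (n_boot < 1L) stop("n_boot must be at least 1")
  if (missing(seed)) stop("bootstrap_mean_ci: 'seed' is required")
  means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    colMeans(matrix(values[idx], nrow = n))
  })
  alpha <- (1 - level) / 2
  qs <- unname(quantile(means, c(alpha, 1 - alpha), na.rm = TRUE))
  list(mean = mean(values), ci_lower = qs[1], ci_upper = qs[2],
       n = n, n_boot = as.integer(n_boot), seed = seed)
}

#' Pearson or Spearman correlation with t-distribution p-value
#'
#' Pairwise-complete observations; Spearman uses mid-ranks for ties. The
#' p-value is two-sided from `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` df
#' (exactly +/-1 coefficients return p = 0).
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `coefficient`, `p_value`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("correlation requires at least 3 complete pairs")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  if (var(x) == 0 || var(y) == 0) stop("zero variance in correlation input")
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(t), df = n - 2, lower.tail = FALSE)
  }
  list(coefficient = r, p_value = p, n = n, method = method)
}

#' Paired summary of one statistic over comparisons
#'
#' Bundles the paired-design inference for one statistic: mean island and
#' mainland values, mean relative island value, percentile bootstrap CI and a
#' Wilcoxon signed-rank test against symmetry about 0.5. Comparisons with
#' undefined relative values are excluded and counted.
#'
#' @param x_island,x_mainland per-comparison statistics (equal length).
#' @param statistic_name label for the summary row.
#' @param tail Wilcoxon tail (see [wilcoxon_signed_rank()]).
#' @param n_boot,seed bootstrap parameters.
#' @param exact_max passed to [wilcoxon_signed_rank()].
#' @return a one-row data.frame (class `paired_summary`): `statistic_name`,
#'   `n_comparisons`, `n_excluded`, `mean_island`, `mean_mainland`,
#'   `mean_relative_island`, `ci_lower`, `ci_upper`, `wilcoxon_p`, `tail`.
#' @export
paired_summary <- function(x_island, x_mainland, statistic_name = "statistic",
                           tail = "two_sided", n_boot = 1000L, seed = 1L,
                           exact_max = 20L) {
  stopifnot(length(x_island) == length(x_mainland))
  rel <- relative_value(x_island, x_mainland)
  ok <- !is.na(rel) & !is.na(x_island) & !is.na(x_mainland)
  n <- sum(ok)
  out <- data.frame(statistic_name = statistic_name, n_comparisons = n,
                    n_excluded = length(rel) - n,
                    mean_island = NA_real_, mean_mainland = NA_real_,
                    mean_relative_island = NA_real_,
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    wilcoxon_p = NA_real_, tail = tail,
                    stringsAsFactors = FALSE)
  if (n == 0L) return(structure(out, class = c("paired_summary", "data.frame")))
  out$mean_island <- mean(x_island[ok])
  out$mean_mainland <- mean(x_mainland[ok])
  out$mean_relative_island <- mean(rel[ok])
  if (n >= 2L) {
    bs <- bootstrap_mean_ci(rel[ok], n_boot = n_boot, seed = seed)
    out$ci_lower <- bs$ci_lower
    out$ci_upper <- bs$ci_upper
  }
  if (any(rel[ok] != 0.5)) {
    out$wilcoxon_p <- wilcoxon_signed_rank(rel[ok], 0.5, tail,
                                           exact_max = exact_max)$p_value
  } else {
    out$wilcoxon_p <- 1  # perfectly symmetric: no evidence against the null
  }
  structure(out, class = c("paired_summary", "data.frame"))
}
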