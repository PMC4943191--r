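test_that("relative_value: equality, zeros, complement identity", {
  expect_equal(relative_value(0.02, 0.02), 0.5)
  expect_equal(relative_value(0, 0.03), 0)
  expect_true(is.na(relative_value(0, 0)))
  expect_error(relative_value(-1, 2), "negative")
  withr::local_seed(2)
  a <- runif(50); b <- runif(50)
  expect_equal(relative_value(a, b) + relative_value(b, a), rep(1, 50))
})

test_that("wilcoxon signed-rank: exact textbook cases", {
  # five values above 0.5, one-tailed greater: p = 1/2^5
  w <- wilcoxon_signed_rank(c(0.6, 0.7, 0.8, 0.9, 0.55), 0.5, "greater")
  expect_equal(w$p_value, 1 / 32)
  expect_true(w$exact)
  # perfect symmetry about the centre: two-sided p = 1
  expect_equal(wilcoxon_signed_rank(c(0.4, 0.6), 0.5, "two_sided")$p_value, 1)
  # zero differences are dropped
  expect_equal(wilcoxon_signed_rank(c(0.5, 0.6, 0.7), 0.5, "greater")$m, 2)
  expect_error(wilcoxon_signed_rank(c(0.5, 0.5), 0.5), "undefined")
})

test_that("wilcoxon exact p matches 2^m sign enumeration (with ties) and wilcox.test", {
  withr::local_seed(17)
  for (k in 1:60) {
    m <- sample(3:12, 1)
    vals <- 0.5 + round(runif(m, -0.4, 0.4), sample(1:2, 1))  # rounding makes ties
    vals <- vals[vals != 0.5]
    if (length(vals) < 2) next
    tail <- sample(c("less", "greater", "two_sided"), 1)
    got <- wilcoxon_signed_rank(vals, 0.5, tail)$p_value
    expect_equal(got, oracle_wilcoxon(vals, 0.5, tail), tolerance = 1e-12,
                 label = paste("m =", length(vals), tail))
  }
  # second independent oracle on tie-free data
  for (k in 1:20) {
    vals <- 0.5 + runif(8, -0.4, 0.4)
    got <- wilcoxon_signed_rank(vals, 0.5, "two_sided")$p_value
    want <- stats::wilcox.test(vals, mu = 0.5, exact = TRUE)$p.value
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("wilcoxon normal approximation is sane for m > exact threshold", {
  withr::local_seed(23)
  vals <- 0.5 + runif(40, -0.3, 0.3)
  appr <- wilcoxon_signed_rank(vals, 0.5, "two_sided")$p_value
  ref <- stats::wilcox.test(vals, mu = 0.5, exact = FALSE,
                            correct = TRUE)$p.value
  expect_false(wilcoxon_signed_rank(vals, 0.5, "two_sided")$exact)
  expect_equal(appr, ref, tolerance = 1e-8)
  # one-tailed type-I calibration on plain gaussian data, exact branch
  reps <- 2000
  pv <- vapply(seq_len(reps), function(i) {
    with_seed(i, wilcoxon_signed_rank(rnorm(15, 0.5, 0.1), 0.5,
                                      "less")$p_value)
  }, 0)
  expect_lt(abs(mean(pv <= 0.05) - 0.05), 0.02)
})

test_that("bootstrap percentile CI: degenerate data, determinism, shrinkage, coverage", {
  cst <- bootstrap_mean_ci(rep(0.5, 8), seed = 1)
  expect_equal(c(cst$mean, cst$ci_lower, cst$ci_upper), c(0.5, 0.5, 0.5))
  expect_error(bootstrap_mean_ci(c(0.1), seed = 1), "at least 2")
  expect_error(bootstrap_mean_ci(c(0.1, 0.2), n_boot = 0, seed = 1), "n_boot")

  withr::local_seed(3)
  x <- runif(25)
  b1 <- bootstrap_mean_ci(x, seed = 42)
  b2 <- bootstrap_mean_ci(x, seed = 42)
  expect_identical(b1, b2)
  expect_equal(b1$mean, mean(x))

  # two independent big-replicate runs agree within Monte-Carlo tolerance
  h1 <- bootstrap_mean_ci(x, n_boot = 1e5, seed = 7)
  h2 <- bootstrap_mean_ci(x, n_boot = 1e5, seed = 8)
  expect_lt(abs(h1$ci_lower - h2$ci_lower), 0.01)
  expect_lt(abs(h1$ci_upper - h2$ci_upper), 0.01)

  # CI width shrinks with sample size
  withr::local_seed(5)
  w <- vapply(c(10, 40), function(n) {
    mean(vapply(1:40, function(i) {
      ci <- bootstrap_mean_ci(runif(n), seed = i)
      ci$ci_upper - ci$ci_lower
    }, 0))
  }, 0)
  expect_lt(w[2], w[1])

  # ~95% coverage of the true mean on simulated data
  reps <- 1000
  hits <- vapply(seq_len(reps), function(i) {
    x <- with_seed(10000 + i, rbeta(30, 2, 2))  # true mean 0.5
    ci <- bootstrap_mean_ci(x, n_boot = 400, seed = i)
    ci$ci_lower <= 0.5 && 0.5 <= ci$ci_upper
  }, TRUE)
  expect_lt(abs(mean(hits) - 0.95), 0.03)
})

test_that("correlate: limits, oracle agreement, error cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, x)$coefficient, 1)
  expect_equal(correlate(x, -x)$coefficient, -1)
  expect_error(correlate(x, rep(1, 5)), "zero variance")
  expect_error(correlate(1:2, 1:2), "at least 3")
  withr::local_seed(29)
  for (k in 1:25) {
    n <- sample(4:8, 1)
    a <- sample(20, n, replace = TRUE)  # replacement makes ties
    b <- sample(20, n, replace = TRUE)
    if (var(a) == 0 || var(b) == 0) next
    if (var(rank(a)) == 0 || var(rank(b)) == 0) next
    expect_equal(correlate(a, b, "spearman")$coefficient,
                 oracle_spearman(a, b), tolerance = 1e-12)
    ref <- stats::cor.test(a, b, method = "pearson")
    got <- correlate(a, b, "pearson")
    expect_equal(got$coefficient, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("paired_summary bundles exclusions, CI ordering and the Wilcoxon", {
  xi <- c(0.02, 0, 0, 0.05, 0.01)
  xm <- c(0.02, 0.03, 0, 0.02, 0.04)
  ps <- paired_summary(xi, xm, "pi_S", tail = "less", seed = 4)
  expect_equal(ps$n_comparisons, 4)  # the (0,0) pair is excluded
  expect_equal(ps$n_excluded, 1)
  expect_true(ps$ci_lower <= ps$mean_relative_island)
  expect_true(ps$mean_relative_island <= ps$ci_upper)
  expect_true(ps$wilcoxon_p > 0 && ps$wilcoxon_p <= 1)
  # all-equal inputs: relative values exactly 0.5, two-sided p = 1
  ps2 <- paired_summary(c(1, 2, 3), c(1, 2, 3), seed = 4)
  expect_equal(ps2$mean_relative_island, 0.5)
  expect_equal(ps2$wilcoxon_p, 1)
})
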