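test_that("fold changes follow the increase/decrease magnitude convention", {
  up <- fold_change(rep(1, 5), rep(2.87, 5))
  expect_equal(up$magnitude, 2.87)
  expect_equal(up$direction, "increase")
  down <- fold_change(rep(1.41, 5), rep(1, 5))
  expect_equal(down$magnitude, 1.41)
  expect_equal(down$direction, "decrease")
  flat <- fold_change(c(1, 2, 3), c(3, 2, 1))
  expect_equal(flat$magnitude, 1)
  expect_equal(flat$direction, "none")
  expect_error(fold_change(c(-2, 0, 2), c(1, 2, 3)), "positive")
})

test_that("exact Mann-Whitney enumeration reproduces the textbook case", {
  res <- compare_two_groups(c(1, 2, 3), c(4, 5, 6), test = "wilcoxon")
  expect_equal(res$test_name, "mann_whitney_u_exact")
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 0.1)
})

test_that("exact enumeration agrees with wilcox.test and the brute oracle", {
  set.seed(99)
  for (i in 1:15) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    a <- round(rnorm(na), 2); b <- round(rnorm(nb, 0.5), 2)
    mine <- compare_two_groups(a, b, test = "wilcoxon")$p_value
    expect_equal(mine, brute_mwu_p(a, b))
    if (!anyDuplicated(c(a, b))) {
      expect_equal(mine, wilcox.test(a, b, exact = TRUE)$p.value)
    }
  }
  # ties force the enumeration path wilcox.test cannot take
  a <- c(1, 1, 2, 3); b <- c(2, 3, 3, 4)
  expect_equal(compare_two_groups(a, b, test = "wilcoxon")$p_value,
               brute_mwu_p(a, b))
})

test_that("identical and degenerate samples give p = 1", {
  x <- c(1, 2, 3, 4)
  res <- compare_two_groups(x, x, test = "wilcoxon")
  expect_equal(res$p_value, 1)
  deg <- compare_two_groups(rep(2, 5), rep(2, 6))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("the normality gate picks the branch per group at alpha", {
  set.seed(7)
  skewed <- exp(rnorm(40, 0, 1.5))
  normal <- rnorm(40, 10)
  res <- compare_two_groups(skewed, normal)
  expect_equal(res$test_name, "mann_whitney_u")
  a <- rnorm(40); b <- rnorm(40, 1)
  res2 <- compare_two_groups(a, b)
  expect_equal(res2$test_name, "welch_t")
  expect_equal(res2$p_value, t.test(a, b)$p.value)
})

test_that("normal-approximation p stays within 0.02 of exact at n = 8", {
  set.seed(11)
  for (i in 1:100) {
    a <- rnorm(8); b <- rnorm(8, 0.8)
    approx_p <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    exact_p <- compare_two_groups(a, b, test = "wilcoxon")$p_value
    expect_lt(abs(approx_p - exact_p), 0.02)
  }
})

test_that("Kruskal-Wallis and Dunn match brute-force rank arithmetic", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  res <- compare_multi_groups(g, test = "kruskal")
  oracle <- brute_kruskal_dunn(g)
  expect_equal(unname(res$statistic), oracle$H)
  expect_equal(res$pairwise$statistic, oracle$z, tolerance = 1e-12)
  expect_equal(res$pairwise$adjusted_p,
               pmin(1, 3 * res$pairwise$raw_p))
  # and with ties
  gt <- list(a = c(1, 1, 2, 4), b = c(2, 3, 3, 5), c = c(5, 6, 6, 9))
  res_t <- compare_multi_groups(gt, test = "kruskal")
  oracle_t <- brute_kruskal_dunn(gt)
  expect_equal(unname(res_t$statistic), oracle_t$H)
  expect_equal(unname(kruskal.test(unlist(gt),
                                   factor(rep(names(gt), each = 4)))$statistic),
               oracle_t$H)  # stats agrees with the oracle too
  if (nrow(res_t$pairwise) > 0) {
    expect_equal(res_t$pairwise$statistic, oracle_t$z, tolerance = 1e-12)
  }
})

test_that("identical groups give a null omnibus and no pairwise rows", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  res <- compare_multi_groups(g, test = "kruskal")
  expect_gt(res$p_value, 0.99)
  expect_equal(nrow(res$pairwise), 0)
})

test_that("Dunn decisions are invariant to group input order", {
  set.seed(3)
  g <- list(a = rlnorm(12), b = rlnorm(12, 1), c = rlnorm(12, 2))
  r1 <- compare_multi_groups(g, test = "kruskal")
  r2 <- compare_multi_groups(g[c("c", "a", "b")], test = "kruskal")
  key <- function(pw) {
    k <- apply(cbind(pmin(pw$group_a, pw$group_b),
                     pmax(pw$group_a, pw$group_b)), 1, paste,
               collapse = "|")
    stats::setNames(pw$adjusted_p, k)[order(k)]
  }
  expect_equal(key(r1$pairwise), key(r2$pairwise))
})

test_that("ANOVA branch matches aov and TukeyHSD", {
  set.seed(5)
  g <- list(a = rnorm(15), b = rnorm(15, 1.5), c = rnorm(15, 3))
  res <- compare_multi_groups(g, test = "anova")
  vals <- unlist(g)
  fac <- factor(rep(names(g), each = 15))
  fit <- aov(vals ~ fac)
  expect_equal(unname(res$statistic), summary(fit)[[1]][["F value"]][1])
  tk <- TukeyHSD(fit)$fac
  expect_equal(sort(res$pairwise$adjusted_p), sort(unname(tk[, "p adj"])),
               tolerance = 1e-8)
  expect_true(all(res$pairwise$adjusted_p >= res$pairwise$raw_p - 1e-12))
})

test_that("adjusted p values always lie in [raw_p, 1]", {
  set.seed(8)
  for (i in 1:10) {
    g <- list(a = rlnorm(10), b = rlnorm(10, 0.5), c = rlnorm(10, 1),
              d = rlnorm(10, 0.2))
    res <- compare_multi_groups(g, test = "kruskal")
    if (nrow(res$pairwise) > 0) {
      expect_true(all(res$pairwise$adjusted_p >= res$pairwise$raw_p))
      expect_true(all(res$pairwise$adjusted_p <= 1))
    }
  }
})

test_that("two-group test has >= 80% power at the hub study's effect size", {
  # lognormal alternatives at the observed fold and sample sizes
  set.seed(17)
  hits <- 0L
  n_rep <- 1000L
  for (i in seq_len(n_rep)) {
    a <- rlnorm(37, 0, 0.6)
    b <- rlnorm(47, log(2.87), 0.6)
    if (compare_two_groups(a, b)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("proportions test matches hand arithmetic and Fisher approximately", {
  eq <- proportion_test(5, 10, 10, 20)
  expect_equal(eq$p_value, 1)
  res <- proportion_test(8, 10, 2, 10)
  # hand chi-square with continuity correction on the 2x2 table
  O <- matrix(c(8, 2, 2, 8), 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  chi <- sum((abs(O - E) - 0.5)^2 / E)
  expect_equal(unname(res$statistic), chi)
  expect_equal(res$p_value, pchisq(chi, 1, lower.tail = FALSE))
  fis <- fisher.test(O)$p.value
  expect_lt(abs(res$p_value - fis), 0.02)
})

test_that("Wilson intervals behave at the boundaries", {
  ci0 <- wilson_ci(0, 10)
  expect_equal(unname(ci0["lower"]), 0)
  expect_gt(ci0["upper"], 0)
  ci1 <- wilson_ci(10, 10)
  expect_equal(unname(ci1["upper"]), 1)
  ci <- wilson_ci(7, 10)
  expect_true(ci["lower"] < 0.7 && ci["upper"] > 0.7)
})

test_that("raincloud summaries use type-7 quantiles and 1.5 IQR whiskers", {
  rs <- summarize_raincloud(list(g = 1:100))
  s <- rs$summary
  expect_equal(s$median, 50.5)
  expect_equal(s$q1, unname(quantile(1:100, 0.25)))
  expect_equal(s$q3, unname(quantile(1:100, 0.75)))
  expect_gte(s$whisker_low, 1)
  expect_lte(s$whisker_high, 100)
  one <- summarize_raincloud(list(g = 5))$summary
  expect_true(all(one[, c("median", "q1", "q3", "whisker_low",
                          "whisker_high")] == 5))
  const <- summarize_raincloud(list(g = rep(3, 8)))$summary
  expect_equal(const$q3 - const$q1, 0)
  expect_equal(const$n_outliers, 0)
  # outliers are flagged, not dropped
  out <- summarize_raincloud(list(g = c(rep(1:5, 4), 50)))
  expect_equal(sum(out$points$outlier), 1)
  expect_equal(out$summary$n, 21)
})
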