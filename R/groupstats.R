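#' Fold change between two groups of measurements
#'
#' The ratio of arithmetic group means, reported by convention as an
#' x-fold increase or decrease with magnitude >= 1: a control mean of 1.0
#' and an experimental mean of 2.87 is a "2.87-fold increase"; reversed, a
#' "2.87-fold decrease".
#'
#' @param control,experimental numeric samples; the control mean must be
#'   positive.
#' @return An object of class `fold_change` with fields `direction`
#'   (`"increase"`, `"decrease"` or `"none"`), `magnitude` (>= 1), `ratio`
#'   (experimental mean / control mean) and the two group means.
#' @examples
#' fold_change(c(0.9, 1.0, 1.1), c(2.7, 2.9, 3.0))
#' @export
fold_change <- function(control, experimental) {
  stopifnot(length(control) > 0, length(experimental) > 0)
  m_c <- mean(control)
  m_e <- mean(experimental)
  if (!is.finite(m_c) || m_c <= 0) stop("control mean must be positive")
  ratio <- m_e / m_c
  structure(list(
    direction = if (ratio > 1) "increase" else if (ratio < 1) "decrease"
                else "none",
    magnitude = max(ratio, 1 / ratio),
    ratio = ratio, mean_control = m_c, mean_experimental = m_e),
    class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  if (x$direction == "none") {
    cat("no fold change (equal means)\n")
  } else {
    cat(sprintf("%.3g-fold %s (means %.4g -> %.4g)\n", x$magnitude,
                x$direction, x$mean_control, x$mean_experimental))
  }
  invisible(x)
}

# Shapiro-Wilk p with guards: zero-variance groups count as non-normal
shapiro_p <- function(x) {
  if (length(x) < 3 || var(x) == 0) return(0)
  shapiro.test(x)$p.value
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments
# (tie-aware; feasible for the small-n regime it is reserved for).
mwu_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  cmb <- combn(n, na)
  us <- colSums(matrix(r[cmb], nrow = na)) - na * (na + 1) / 2
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p = min(1, p))
}

#' Compare two independent groups with a normality-gated test
#'
#' The decision tree applied to density cohorts: Shapiro-Wilk normality is
#' checked per group at level `alpha`; if either group fails, a two-sided
#' Mann-Whitney U test is used (exact enumeration, tie-aware, when both
#' groups have at most `exact_max_n` observations; otherwise the
#' tie-corrected normal approximation with continuity correction). If both
#' groups pass, a two-sided unpaired t test is used — Welch by default,
#' pooled-variance ("Student") via `var_equal = TRUE`.
#'
#' @param a,b numeric samples, `n >= 3` each; `a` is treated as the
#'   control for the reported fold change.
#' @param alpha significance level for the normality gate.
#' @param test `"auto"` applies the gate; `"wilcoxon"` or `"t"` force a
#'   branch.
#' @param labels length-2 character vector naming the groups.
#' @param var_equal use the pooled-variance t test instead of Welch.
#' @param exact_max_n largest per-group n for exact Mann-Whitney
#'   enumeration.
#' @return A `group_comparison` object: `test_name`, `statistic`,
#'   `p_value`, `pairwise` (one row), `normality_p`, `fold_change`, `n`,
#'   `degenerate` (all values tied).
#' @examples
#' compare_two_groups(c(1, 2, 3), c(4, 5, 6), test = "wilcoxon")
#' @export
compare_two_groups <- function(a, b, alpha = 0.05,
                               test = c("auto", "wilcoxon", "t"),
                               labels = c("a", "b"), var_equal = FALSE,
                               exact_max_n = 8L) {
  test <- match.arg(test)
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 3, length(b) >= 3, length(labels) == 2)
  norm_p <- c(shapiro_p(a), shapiro_p(b))
  names(norm_p) <- labels
  # fold change is undefined for non-positive control means (density data
  # are positive; general inputs need not be)
  fc <- tryCatch(fold_change(a, b), error = function(e) NULL)
  degenerate <- var(c(a, b)) == 0
  if (degenerate) {
    res <- list(test_name = "degenerate", statistic = NA_real_,
                p_value = 1)
  } else {
    branch <- switch(test,
                     auto = if (any(norm_p < alpha)) "wilcoxon" else "t",
                     test)
    if (branch == "wilcoxon") {
      if (length(a) <= exact_max_n && length(b) <= exact_max_n) {
        ex <- mwu_exact(a, b)
        res <- list(test_name = "mann_whitney_u_exact", statistic = ex$u,
                    p_value = ex$p)
      } else {
        w <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                          correct = TRUE))
        res <- list(test_name = "mann_whitney_u",
                    statistic = unname(w$statistic), p_value = w$p.value)
      }
    } else {
      tt <- t.test(a, b, var.equal = var_equal)
      res <- list(test_name = if (var_equal) "student_t" else "welch_t",
                  statistic = unname(tt$statistic), p_value = tt$p.value)
    }
  }
  pairwise <- data.frame(group_a = labels[1], group_b = labels[2],
                         statistic = res$statistic, raw_p = res$p_value,
                         adjusted_p = res$p_value)
  structure(list(test_name = res$test_name, statistic = res$statistic,
                 p_value = res$p_value, pairwise = pairwise,
                 normality_p = norm_p, fold_change = fc,
                 n = stats::setNames(c(length(a), length(b)), labels),
                 alpha = alpha, degenerate = degenerate),
            class = "group_comparison")
}

# Dunn's post hoc z tests on pooled ranks, with the tie correction and
# Bonferroni multiplication over all unordered pairs.
dunn_test <- function(values, groups) {
  g <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  labs <- levels(g)
  pairs <- combn(length(labs), 2)
  m <- ncol(pairs)
  out <- data.frame(group_a = labs[pairs[1, ]], group_b = labs[pairs[2, ]],
                    statistic = NA_real_, raw_p = NA_real_,
                    adjusted_p = NA_real_)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(v0 * (1 / n[i1] + 1 / n[i2]))
    z <- (rbar[i1] - rbar[i2]) / se
    p <- 2 * pnorm(-abs(z))
    out$statistic[j] <- z
    out$raw_p[j] <- p
    out$adjusted_p[j] <- min(1, m * p)
  }
  out
}

# Tukey HSD on a one-way layout: studentized-range adjusted p plus the
# unadjusted pooled-variance pairwise p for reference.
tukey_pairs <- function(values, groups) {
  g <- factor(groups)
  labs <- levels(g)
  k <- length(labs)
  n <- tapply(values, g, length)
  means <- tapply(values, g, mean)
  df <- length(values) - k
  mse <- sum(tapply(values, g, function(x) sum((x - mean(x))^2))) / df
  pairs <- combn(k, 2)
  out <- data.frame(group_a = labs[pairs[1, ]], group_b = labs[pairs[2, ]],
                    statistic = NA_real_, raw_p = NA_real_,
                    adjusted_p = NA_real_)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(mse * (1 / n[i1] + 1 / n[i2]))
    tstat <- (means[i2] - means[i1]) / se
    out$statistic[j] <- tstat
    out$raw_p[j] <- 2 * pt(-abs(tstat), df)
    out$adjusted_p[j] <- ptukey(abs(tstat) * sqrt(2), k, df,
                                lower.tail = FALSE)
  }
  out
}

#' Compare three or more groups with a normality-gated omnibus test
#'
#' Shapiro-Wilk is applied to every group; if any group fails at `alpha`
#' the nonparametric branch runs a Kruskal-Wallis test (tie-corrected)
#' followed, when the omnibus is significant, by all-pairs Dunn z tests
#' with Bonferroni correction. Otherwise one-way ANOVA followed by Tukey's
#' HSD. Pairwise results are reported only when the omnibus p is below
#' `alpha`.
#'
#' @param groups named list of numeric samples (>= 3 groups, n >= 3 each).
#' @param alpha significance level for the gate, the omnibus test and the
#'   pairwise reporting rule.
#' @param test `"auto"`, `"kruskal"` or `"anova"`.
#' @param control optional group name; when given, fold changes of every
#'   other group against it are reported.
#' @return A `group_comparison` object with `test_name`
#'   (`"kruskal_wallis_dunn"` or `"anova_tukey"`), omnibus `statistic` and
#'   `p_value`, a `pairwise` data frame (`group_a`, `group_b`,
#'   `statistic`, `raw_p`, `adjusted_p`), `normality_p`, `fold_changes`
#'   and `n` per group. Zero-variance groups alongside nondegenerate ones
#'   are flagged in `flags`.
#' @examples
#' g <- list(ctrl = c(1, 2, 3), t1 = c(4, 5, 6), t2 = c(7, 8, 9))
#' compare_multi_groups(g, test = "kruskal")
#' @export
compare_multi_groups <- function(groups, alpha = 0.05,
                                 test = c("auto", "kruskal", "anova"),
                                 control = NULL) {
  test <- match.arg(test)
  stopifnot(is.list(groups), length(groups) >= 3,
            !is.null(names(groups)), all(nchar(names(groups)) > 0))
  if (any(vapply(groups, length, 0L) < 3)) {
    stop("every group needs n >= 3")
  }
  labs <- names(groups)
  values <- unlist(groups, use.names = FALSE)
  gfac <- factor(rep(labs, vapply(groups, length, 0L)), levels = labs)
  norm_p <- vapply(groups, shapiro_p, 0)
  flags <- character(0)
  zero_var <- vapply(groups, function(x) var(x) == 0, TRUE)
  if (any(zero_var) && !all(zero_var)) {
    flags <- c(flags, paste0("zero-variance group(s): ",
                             paste(labs[zero_var], collapse = ", ")))
  }
  branch <- switch(test,
                   auto = if (any(norm_p < alpha)) "kruskal" else "anova",
                   test)
  if (branch == "kruskal") {
    kw <- kruskal.test(values, gfac)
    omnibus <- unname(kw$statistic)
    omnibus_p <- kw$p.value
    pairwise <- if (is.finite(omnibus_p) && omnibus_p < alpha) {
      dunn_test(values, gfac)
    } else {
      empty_pairwise()
    }
    test_name <- "kruskal_wallis_dunn"
  } else {
    fit <- aov(values ~ gfac)
    tab <- summary(fit)[[1]]
    omnibus <- tab[["F value"]][1]
    omnibus_p <- tab[["Pr(>F)"]][1]
    pairwise <- if (is.finite(omnibus_p) && omnibus_p < alpha) {
      tukey_pairs(values, gfac)
    } else {
      empty_pairwise()
    }
    test_name <- "anova_tukey"
  }
  fcs <- NULL
  if (!is.null(control)) {
    stopifnot(control %in% labs)
    fcs <- lapply(groups[setdiff(labs, control)],
                  function(x) fold_change(groups[[control]], x))
  }
  structure(list(test_name = test_name, statistic = omnibus,
                 p_value = omnibus_p, pairwise = pairwise,
                 normality_p = norm_p, fold_changes = fcs,
                 n = vapply(groups, length, 0L), alpha = alpha,
                 flags = flags, degenerate = all(zero_var)),
            class = "group_comparison")
}

empty_pairwise <- function() {
  data.frame(group_a = character(), group_b = character(),
             statistic = numeric(), raw_p = numeric(),
             adjusted_p = numeric())
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat("Group comparison:", x$test_name, "\n")
  cat(sprintf("  omnibus statistic = %.*g, p = %.*g\n", digits,
              x$statistic, digits, x$p_value))
  cat("  n:", paste(sprintf("%s=%d", names(x$n), x$n), collapse = ", "),
      "\n")
  cat("  Shapiro-Wilk p:",
      paste(sprintf("%s=%.3g", names(x$normality_p), x$normality_p),
            collapse = ", "), "\n")
  if (nrow(x$pairwise) > 0) {
    cat("  pairwise (adjusted):\n")
    pw <- x$pairwise
    for (i in seq_len(nrow(pw))) {
      cat(sprintf("    %s vs %s: p = %.3g\n", pw$group_a[i], pw$group_b[i],
                  pw$adjusted_p[i]))
    }
  }
  if (!is.null(x$fold_changes)) {
    for (nm in names(x$fold_changes)) {
      fc <- x$fold_changes[[nm]]
      cat(sprintf("  %s: %.3g-fold %s\n", nm, fc$magnitude, fc$direction))
    }
  }
  if (length(x$flags %||% character(0)) > 0) {
    cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Two-proportion test with Wilson confidence intervals
#'
#' Two-sided two-proportion chi-square test with continuity correction
#' (as used for cell-type tropism proportions), plus the per-group Wilson
#' score 95% confidence intervals that accompany such proportions.
#'
#' @param k1,n1,k2,n2 successes and totals for the two groups.
#' @param conf_level confidence level of the Wilson intervals.
#' @param correct apply the continuity correction.
#' @return A list: `p_value`, `estimate` (the two proportions), `ci1`,
#'   `ci2` (Wilson intervals), `statistic` (chi-square).
#' @examples
#' proportion_test(8, 10, 2, 10)
#' @export
proportion_test <- function(k1, n1, k2, n2, conf_level = 0.95,
                            correct = TRUE) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  pt <- suppressWarnings(prop.test(c(k1, k2), c(n1, n2),
                                   correct = correct))
  list(p_value = pt$p.value, estimate = unname(pt$estimate),
       ci1 = wilson_ci(k1, n1, conf_level),
       ci2 = wilson_ci(k2, n2, conf_level),
       statistic = unname(pt$statistic))
}

#' Wilson score interval for a binomial proportion
#'
#' @param k,n successes and trials.
#' @param conf_level confidence level.
#' @return Named vector `c(lower, upper)`.
#' @export
wilson_ci <- function(k, n, conf_level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Box-and-whisker summaries for raincloud-style displays
#'
#' Per group: median, quartiles (linear-interpolation quantiles, R type 7),
#' whiskers at the most extreme data points within 1.5 x IQR of the box,
#' and an outlier flag per observation — the numbers shown by a raincloud
#' plot (points + box/whiskers + half-violin).
#'
#' @param groups named list of numeric samples.
#' @param whisker_mult whisker reach in IQR multiples.
#' @return A `raincloud_summary`: `summary` (one row per group: `group`,
#'   `n`, `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `n_outliers`) and `points` (long format: `group`, `value`,
#'   `outlier`).
#' @examples
#' summarize_raincloud(list(ctrl = rlnorm(20), rnai = rlnorm(20, 1)))
#' @export
summarize_raincloud <- function(groups, whisker_mult = 1.5) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  summ <- do.call(rbind, lapply(names(groups), function(nm) {
    x <- groups[[nm]]
    stopifnot(length(x) >= 1)
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - whisker_mult * iqr
    hi_fence <- q[3] + whisker_mult * iqr
    inside <- x >= lo_fence & x <= hi_fence
    data.frame(group = nm, n = length(x), median = q[2], q1 = q[1],
               q3 = q[3], whisker_low = min(x[inside]),
               whisker_high = max(x[inside]), n_outliers = sum(!inside))
  }))
  points <- do.call(rbind, lapply(names(groups), function(nm) {
    x <- groups[[nm]]
    s <- summ[summ$group == nm, ]
    data.frame(group = nm, value = x,
               outlier = x < s$whisker_low | x > s$whisker_high)
  }))
  rownames(summ) <- rownames(points) <- NULL
  structure(list(summary = summ, points = points), class = "raincloud_summary")
}

#' @export
print.raincloud_summary <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Raincloud-style plot of grouped measurements
#'
#' Jittered points beside a box-and-whisker summary and a half-violin,
#' built from [summarize_raincloud()]. Requires ggplot2.
#'
#' @param groups named list of numeric samples.
#' @param ylab y-axis label.
#' @return A ggplot object.
#' @export
plot_raincloud <- function(groups, ylab = "relative density") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_raincloud requires the ggplot2 package")
  }
  rs <- summarize_raincloud(groups)
  pts <- rs$points
  ggplot2::ggplot(pts, ggplot2::aes(x = group, y = value)) +
    ggplot2::geom_violin(alpha = 0.3, trim = FALSE) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}
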