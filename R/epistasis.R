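#' Expected fold change of two perturbations under the additive model
#'
#' Under the additive (independent-pathways) model, the combined fold
#' change expected from two perturbations that individually increase the
#' phenotype `fold_a`-fold and `fold_b`-fold is their sum: singles of 2.33
#' and 3.89 give an expectation of 6.22, singles of 2 and 3 give 5. The
#' literal sum is the model's stated combination rule; note its known
#' artifact that two null perturbations (1, 1) give an expectation of 2
#' rather than 1. The alternative `rule = "deviation"` sums deviations
#' from 1 instead (`fold_a + fold_b - 1`), which removes that artifact and
#' is provided for sensitivity analyses.
#'
#' The rule is defined for increases only; decrease-direction folds are an
#' error.
#'
#' @param fold_a,fold_b fold-change magnitudes (>= 1) or [fold_change()]
#'   objects with direction `"increase"` (or `"none"`).
#' @param rule `"sum"` (the additive model's literal rule, default) or
#'   `"deviation"`.
#' @return The expected combined fold change (scalar).
#' @examples
#' expected_additive(2.33, 3.89)  # 6.22
#' expected_additive(2, 3)        # 5
#' @export
expected_additive <- function(fold_a, fold_b, rule = c("sum", "deviation")) {
  rule <- match.arg(rule)
  fold_a <- as_fold_magnitude(fold_a)
  fold_b <- as_fold_magnitude(fold_b)
  if (rule == "sum") fold_a + fold_b else fold_a + fold_b - 1
}

as_fold_magnitude <- function(f) {
  if (inherits(f, "fold_change")) {
    if (f$direction == "decrease") {
      stop("the additive expectation is defined for increases only")
    }
    return(f$magnitude)
  }
  stopifnot(is.numeric(f), length(f) == 1)
  if (f < 1) {
    stop("the additive expectation is defined for increases only ",
         "(fold >= 1); got ", f)
  }
  f
}

#' Classify a four-group epistasis design
#'
#' Given a control, two single perturbations and their combination, runs
#' the normality-gated multi-group comparison over all four groups and
#' applies the decision table used to place two genes in the same or in
#' independent pathways:
#'
#' \itemize{
#'   \item no group differs from the control (or the omnibus test is not
#'     significant) -> `no_effect`;
#'   \item the combined group differs from the control, does \emph{not}
#'     differ from single X, and does differ from single Y ->
#'     `same_pathway_as_X` (matching one single's phenotype indicates a
#'     shared pathway);
#'   \item the combined group differs from the control and from both
#'     singles, and its fold change is closer (absolute distance on the
#'     fold scale) to the additive expectation than to either single fold
#'     -> `independent_additive`;
#'   \item otherwise -> `inconclusive`.
#' }
#'
#' "Does not differ" is failure to reject at the multiplicity-adjusted
#' `alpha` — an accept-the-null heuristic, flagged as such in the result;
#' it is not an equivalence test.
#'
#' @param control,single_a,single_b,combined numeric samples (n >= 3).
#' @param alpha significance level used throughout.
#' @param labels length-2 names for the two single perturbations.
#' @param rule additive combination rule, see [expected_additive()].
#' @param test passed to [compare_multi_groups()] (`"auto"` gates on
#'   normality).
#' @param adjust which pairwise p value the verdict table consumes:
#'   `"bonferroni"` (default; the multiplicity-corrected p, matching how
#'   the underlying post hoc tests are reported) or `"none"` (raw pairwise
#'   p). The Bonferroni default makes the accept-the-null similarity check
#'   conservative: with four groups the combined-vs-single comparison
#'   loses appreciable power at moderate effect sizes, so shared-pathway
#'   verdicts are favoured near the decision boundary; `"none"` trades
#'   that for a higher false-difference rate.
#' @return A `wolbaq_epistasis` object: `verdict`, `fold_a`, `fold_b`,
#'   `fold_combined` ([fold_change()] objects), `expected_additive` (NA if
#'   either single is a decrease), `comparison` (the full
#'   [compare_multi_groups()] result), `labels`, `flags`.
#' @examples
#' g <- simulate_cohort(data.frame(
#'   label = c("control", "CifB", "Atg1_RNAi", "CifB_Atg1_RNAi"),
#'   n = 30, mean_log = log(c(1, 2.33, 3.89, 3.89)), sd_log = 0.3),
#'   seed = 42)
#' sam <- split(g$relative_density, g$group)
#' classify_epistasis(sam$control, sam$CifB, sam$Atg1_RNAi,
#'                    sam$CifB_Atg1_RNAi, labels = c("CifB", "Atg1_RNAi"))
#' @export
classify_epistasis <- function(control, single_a, single_b, combined,
                               alpha = 0.05, labels = c("A", "B"),
                               rule = c("sum", "deviation"),
                               test = c("auto", "kruskal", "anova"),
                               adjust = c("bonferroni", "none")) {
  rule <- match.arg(rule)
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  stopifnot(length(labels) == 2, length(control) >= 3,
            length(single_a) >= 3, length(single_b) >= 3,
            length(combined) >= 3)
  lab_ab <- paste(labels, collapse = "+")
  groups <- stats::setNames(list(control, single_a, single_b, combined),
                            c("control", labels, lab_ab))
  cmp <- compare_multi_groups(groups, alpha = alpha, test = test,
                              control = "control")
  f_a <- fold_change(control, single_a)
  f_b <- fold_change(control, single_b)
  f_ab <- fold_change(control, combined)
  expected <- if (f_a$direction != "decrease" &&
                  f_b$direction != "decrease") {
    expected_additive(f_a, f_b, rule = rule)
  } else {
    NA_real_
  }
  flags <- c("similarity is failure to reject at adjusted alpha, not an equivalence test")

  adj_p <- function(g1, g2) {
    pw <- cmp$pairwise
    hit <- (pw$group_a == g1 & pw$group_b == g2) |
      (pw$group_a == g2 & pw$group_b == g1)
    if (!any(hit)) return(NA_real_)
    if (adjust == "bonferroni") pw$adjusted_p[hit][1] else pw$raw_p[hit][1]
  }

  if (!is.finite(cmp$p_value) || cmp$p_value >= alpha) {
    verdict <- "no_effect"
    if (f_a$magnitude > 1.25 || f_b$magnitude > 1.25) {
      flags <- c(flags,
                 "omnibus not significant despite sizeable single folds")
    }
  } else {
    p_a_c <- adj_p("control", labels[1])
    p_b_c <- adj_p("control", labels[2])
    p_ab_c <- adj_p("control", lab_ab)
    p_ab_a <- adj_p(labels[1], lab_ab)
    p_ab_b <- adj_p(labels[2], lab_ab)
    sig <- function(p) is.finite(p) && p < alpha
    if (!sig(p_a_c) && !sig(p_b_c) && !sig(p_ab_c)) {
      verdict <- "no_effect"
    } else if (sig(p_ab_c) && !sig(p_ab_a) && sig(p_ab_b)) {
      verdict <- "same_pathway_as_a"
    } else if (sig(p_ab_c) && sig(p_ab_a) && !sig(p_ab_b)) {
      verdict <- "same_pathway_as_b"
    } else if (sig(p_ab_c) && sig(p_ab_a) && sig(p_ab_b) &&
               is.finite(expected) &&
               abs(f_ab$ratio - expected) <
                 min(abs(f_ab$ratio - f_a$ratio),
                     abs(f_ab$ratio - f_b$ratio))) {
      verdict <- "independent_additive"
    } else {
      verdict <- "inconclusive"
    }
  }
  structure(list(verdict = verdict, fold_a = f_a, fold_b = f_b,
                 fold_combined = f_ab, expected_additive = expected,
                 comparison = cmp, labels = labels, alpha = alpha,
                 rule = rule, flags = flags),
            class = "wolbaq_epistasis")
}

#' @export
print.wolbaq_epistasis <- function(x, ...) {
  cat("Additive epistasis analysis\n")
  cat(sprintf("  %s: %.3g-fold %s\n", x$labels[1], x$fold_a$magnitude,
              x$fold_a$direction))
  cat(sprintf("  %s: %.3g-fold %s\n", x$labels[2], x$fold_b$magnitude,
              x$fold_b$direction))
  cat(sprintf("  combined: %.3g-fold %s\n", x$fold_combined$magnitude,
              x$fold_combined$direction))
  if (is.finite(x$expected_additive)) {
    cat(sprintf("  additive expectation (%s rule): %.3g-fold\n", x$rule,
                x$expected_additive))
  }
  v <- x$verdict
  if (v == "same_pathway_as_a") v <- paste0("same pathway as ", x$labels[1])
  if (v == "same_pathway_as_b") v <- paste0("same pathway as ", x$labels[2])
  cat("  verdict:", v, "\n")
  invisible(x)
}
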