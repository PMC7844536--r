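#' Rank features by a signed two-group statistic
#'
#' Builds the preranked input for set enrichment from a two-group feature
#' matrix: per feature, a signed Welch t statistic (positive = higher in
#' the first group level), sorted in decreasing order with ties broken by
#' feature id so the ranking is deterministic. Features constant in both
#' groups with equal means score 0; a nonzero mean difference with zero
#' variance is capped at +/- 1e8 (documented sentinel for "infinitely
#' separated").
#'
#' @param mat numeric matrix, features x samples, with row and column
#'   names.
#' @param groups factor or character of length `ncol(mat)` with exactly
#'   two levels, >= 3 samples each.
#' @return Named numeric vector of scores, decreasing.
#' @examples
#' pw <- random_pathways(3, 50, seed = 1)
#' sim <- simulate_metabolome(50, pw, n_per_group = 4, seed = 1)
#' head(rank_features(sim$abundance, sim$groups))
#' @export
rank_features <- function(mat, groups) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)),
            !anyDuplicated(rownames(mat)), length(groups) == ncol(mat))
  g <- if (is.factor(groups)) droplevels(groups) else {
    factor(groups, levels = unique(groups))
  }
  if (nlevels(g) != 2) stop("exactly two groups are required")
  if (any(table(g) < 3)) stop("each group needs >= 3 samples")
  i1 <- g == levels(g)[1]
  x1 <- mat[, i1, drop = FALSE]
  x2 <- mat[, !i1, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  d <- m1 - m2
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * 1e8))
  t <- pmax(pmin(t, 1e8), -1e8)
  names(t) <- rownames(mat)
  t[order(-t, names(t))]
}

#' GSEA-style enrichment score of a feature set in a ranked list
#'
#' Walks the ranked list accumulating a running sum: at a member ("hit")
#' the sum increases by `|score|^weight` normalized by the total over
#' members; at a non-member it decreases by `1/(N - k)`. The enrichment
#' score (ES) is the signed maximum deviation from zero and lies in
#' `[-1, 1]`; when the positive and negative extremes tie in magnitude the
#' positive one is returned. With `weight = 0` every hit counts equally and the ES is
#' invariant to any positive rescaling of the scores.
#'
#' @param ranked named numeric vector as returned by [rank_features()]
#'   (re-sorted defensively with the same tie rule).
#' @param members character vector of feature ids; must intersect the
#'   ranked universe but not cover it.
#' @param weight exponent on `|score|` for hit increments (default 1).
#' @return The ES (scalar in `[-1, 1]`).
#' @examples
#' r <- c(a = 2, b = 1, c = 0, d = -1, e = -2)
#' enrichment_score(r, c("a", "b"), weight = 0)  # +1
#' @export
enrichment_score <- function(ranked, members, weight = 1) {
  ranked <- ranked[order(-ranked, names(ranked))]
  hits <- which(names(ranked) %in% members)
  N <- length(ranked)
  k <- length(hits)
  if (k == 0) stop("no members of the set are in the ranked universe")
  if (k == N) stop("the set covers the whole ranked universe")
  es_from_positions(hits, abs(ranked[hits])^weight, N)
}

# Core running-sum extremum, evaluated only at hit positions (the path is
# linear between hits, so its extrema occur at a hit or just before one,
# or at the endpoint value 0).
es_from_positions <- function(hits, w, N) {
  k <- length(hits)
  tot <- sum(w)
  if (tot == 0) w <- rep(1 / k, k) else w <- w / tot
  ch <- cumsum(w)
  miss <- 1 / (N - k)
  at_hit <- ch - (hits - seq_len(k)) * miss
  before_hit <- c(0, ch[-k]) - (hits - seq_len(k)) * miss
  hi <- max(at_hit)
  lo <- min(before_hit, 0)
  # ties in magnitude (up to float noise) resolve to the positive extreme
  if (hi + lo >= -1e-12) hi else lo
}

#' Permutation-normalized enrichment over a pathway collection
#'
#' For each pathway, the observed ES is compared to a null of random
#' member sets of the same size drawn from the ranked universe (the
#' feature-label permutation used for preranked enrichment; sample-label
#' permutation is impossible from a ranked list alone). The normalized
#' enrichment score is `NES = ES / mean(|ES_null|)` over null draws of the
#' same sign as the observed ES, and the permutation p value uses the
#' add-one estimator `p = (1 + #{|ES_null| >= |ES|, same sign}) /
#' (1 + #same-sign nulls)`, so p is never exactly zero.
#'
#' @param ranked named numeric vector (see [rank_features()]).
#' @param pathways named list of feature-id sets (see [read_gmt()]).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param weight hit-weight exponent, see [enrichment_score()].
#' @param min_size pathways with fewer members in the universe are skipped
#'   with a warning.
#' @param exhaustive enumerate all same-size subsets instead of sampling
#'   (only sensible for tiny universes; overrides `n_perm`).
#' @return Data frame sorted by decreasing `|NES|`: `pathway`, `size`,
#'   `es`, `nes`, `perm_p`.
#' @examples
#' pw <- random_pathways(4, 100, seed = 2)
#' sim <- simulate_metabolome(100, pw, enriched = c(pathway_01 = 2),
#'                            n_per_group = 4, seed = 3)
#' ranked <- rank_features(sim$abundance, sim$groups)
#' normalize_permutation(ranked, pw, n_perm = 200, seed = 4)
#' @export
normalize_permutation <- function(ranked, pathways, n_perm = 1000L,
                                  seed = 1L, weight = 1, min_size = 1L,
                                  exhaustive = FALSE) {
  stopifnot(is.numeric(ranked), !is.null(names(ranked)),
            is.list(pathways), !is.null(names(pathways)),
            exhaustive || n_perm >= 100)
  ranked <- ranked[order(-ranked, names(ranked))]
  N <- length(ranked)
  absw <- abs(ranked)^weight
  local_seed(seed, {
    rows <- lapply(names(pathways), function(pw) {
      hits <- which(names(ranked) %in% pathways[[pw]])
      k <- length(hits)
      if (k < min_size || k >= N) {
        warning("skipping pathway '", pw,
                "': size ", k, " after intersection with the universe")
        return(NULL)
      }
      es <- es_from_positions(hits, absw[hits], N)
      null_es <- if (exhaustive) {
        sets <- combn(N, k)
        apply(sets, 2, function(s) es_from_positions(s, absw[s], N))
      } else {
        vapply(seq_len(n_perm), function(i) {
          s <- sort.int(sample.int(N, k))
          es_from_positions(s, absw[s], N)
        }, 0)
      }
      same_sign <- null_es[sign(null_es) == sign(es)]
      m <- length(same_sign)
      nes <- if (m > 0) es / mean(abs(same_sign)) else NA_real_
      p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + m)
      data.frame(pathway = pw, size = k, es = es, nes = nes, perm_p = p)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      return(data.frame(pathway = character(), size = integer(),
                        es = numeric(), nes = numeric(),
                        perm_p = numeric()))
    }
    out <- out[order(-abs(out$nes), out$pathway, na.last = TRUE), ]
    rownames(out) <- NULL
    out
  })
}

#' Z-score and principal-component overview of a feature matrix
#'
#' Feature-wise z-scoring (constant features are dropped with a warning)
#' followed by PCA over samples — the standard global view of a
#' metabolome: a heat-map-ready standardized matrix plus sample
#' coordinates and the proportion of variance per component.
#'
#' @param mat numeric matrix, features x samples (>= 2 samples, >= 2
#'   non-constant features).
#' @return A `wolbaq_overview`: `zscores` (standardized matrix),
#'   `pc_scores` (samples x components), `variance_explained`
#'   (nonincreasing, sums to 1), `rotation`.
#' @export
overview_pca <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2, nrow(mat) >= 2)
  sds <- apply(mat, 1, sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant feature(s)")
    mat <- mat[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(mat) < 2) stop("fewer than 2 non-constant features")
  z <- (mat - rowMeans(mat)) / sds
  pca <- prcomp(t(z), center = TRUE, scale. = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  structure(list(zscores = z, pc_scores = pca$x,
                 variance_explained = ve, rotation = pca$rotation),
            class = "wolbaq_overview")
}

#' @export
print.wolbaq_overview <- function(x, ...) {
  cat(sprintf("metabolome overview: %d features x %d samples\n",
              nrow(x$zscores), ncol(x$zscores)))
  ve <- x$variance_explained
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(min(3, length(ve))),
                    100 * ve[seq_len(min(3, length(ve)))]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.wolbaq_overview <- function(x, components = c(1, 2), ...) {
  s <- x$pc_scores
  ve <- x$variance_explained
  plot(s[, components[1]], s[, components[2]],
       xlab = sprintf("PC%d (%.1f%%)", components[1],
                      100 * ve[components[1]]),
       ylab = sprintf("PC%d (%.1f%%)", components[2],
                      100 * ve[components[2]]), ...)
  invisible(x)
}

#' Read or write pathway sets in GMT format
#'
#' `read_gmt()` wraps `fgsea::gmtPathways()`; `write_gmt()` writes the
#' standard tab-separated name / description / members lines.
#'
#' @param path file path.
#' @param pathways named list of character vectors.
#' @param description description field written for each pathway.
#' @return `read_gmt` returns a named list of feature-id vectors;
#'   `write_gmt` returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(pathways, path, description = "na") {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, description, pathways[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
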