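test_that("feature ranking matches hand-computed Welch t statistics", {
  mat <- rbind(
    f1 = c(5, 6, 7, 1, 2, 3),
    f2 = c(1, 2, 3, 5, 6, 7),
    f3 = c(2, 2.5, 3, 2, 2.5, 3),
    f4 = c(10, 11, 12, 1, 1.5, 2))
  colnames(mat) <- paste0("s", 1:6)
  groups <- rep(c("A", "B"), each = 3)
  ranked <- rank_features(mat, groups)
  byhand <- sapply(rownames(mat), function(f) {
    t.test(mat[f, 1:3], mat[f, 4:6])$statistic
  })
  expect_equal(unname(ranked[rownames(mat)]), unname(byhand))
  expect_equal(names(ranked)[1], "f4")  # largest positive separation
  # swapping the reference level negates every score and reverses the order
  flipped <- rank_features(mat, factor(groups, levels = c("B", "A")))
  expect_equal(unname(flipped[names(ranked)]), -unname(ranked))
})

test_that("zero-variance separated features rank first with a capped score", {
  mat <- rbind(sep = c(2, 2, 2, 1, 1, 1),
               mid = c(1, 2, 3, 0, 1, 2),
               flat = c(1, 1, 1, 1, 1, 1))
  colnames(mat) <- paste0("s", 1:6)
  ranked <- rank_features(mat, rep(c("A", "B"), each = 3))
  expect_equal(names(ranked)[1], "sep")
  expect_equal(unname(ranked["sep"]), 1e8)
  expect_equal(unname(ranked["flat"]), 0)
})

test_that("enrichment score reproduces the hand-walked running sums", {
  r <- c(a = 2, b = 1, c = 0, d = -1, e = -2)
  expect_equal(enrichment_score(r, c("a", "b"), weight = 0), 1.0)
  expect_equal(enrichment_score(r, c("d", "e"), weight = 0), -1.0)
  # evenly interleaved members in a symmetric score vector stay small
  r6 <- c(a = 3, b = 2, c = 1, d = -1, e = -2, f = -3)
  expect_lt(abs(enrichment_score(r6, c("a", "c", "e"), weight = 0)), 0.5)
  expect_error(enrichment_score(r, c("x", "y")), "no members")
  expect_error(enrichment_score(r, names(r)), "whole ranked universe")
})

test_that("enrichment score agrees with the brute-force walk and stays in [-1, 1]", {
  set.seed(21)
  for (i in 1:50) {
    N <- sample(8:40, 1)
    scores <- stats::setNames(rnorm(N), sprintf("g%03d", seq_len(N)))
    k <- sample(2:(N - 2), 1)
    members <- sample(names(scores), k)
    w <- sample(c(0, 1), 1)
    es <- enrichment_score(scores, members, weight = w)
    expect_equal(es, brute_es(scores, members, weight = w))
    expect_gte(es, -1)
    expect_lte(es, 1)
  }
})

test_that("weight-0 scores are invariant to positive rescaling", {
  set.seed(4)
  scores <- stats::setNames(rnorm(20), letters[1:20])
  members <- c("a", "e", "k", "s")
  expect_equal(enrichment_score(scores, members, weight = 0),
               enrichment_score(scores * 37.5, members, weight = 0))
})

test_that("exhaustive permutation p matches full enumeration on a toy universe", {
  r <- c(a = 2, b = 1, c = 0, d = -1, e = -2)
  pw <- list(top = c("a", "b"))
  res <- normalize_permutation(r, pw, seed = 1, weight = 0,
                               exhaustive = TRUE)
  # oracle: all C(5,2) = 10 member sets, brute running sums
  sets <- utils::combn(names(r), 2)
  null_es <- apply(sets, 2, function(s) brute_es(r, s, weight = 0))
  es_obs <- brute_es(r, pw$top, weight = 0)
  same <- null_es[sign(null_es) == sign(es_obs)]
  p_oracle <- (1 + sum(abs(same) >= abs(es_obs))) / (1 + length(same))
  expect_equal(res$es, 1.0)
  expect_equal(res$perm_p, p_oracle)
  expect_equal(res$nes, es_obs / mean(abs(same)))
})

test_that("permutation tables are seed-deterministic and sign-consistent", {
  pw <- random_pathways(5, 80, seed = 3)
  sim <- simulate_metabolome(80, pw, enriched = c(pathway_02 = 2),
                             n_per_group = 4, seed = 5)
  ranked <- rank_features(sim$abundance, sim$groups)
  r1 <- normalize_permutation(ranked, pw, n_perm = 200, seed = 11)
  r2 <- normalize_permutation(ranked, pw, n_perm = 200, seed = 11)
  expect_identical(r1, r2)
  expect_true(all(sign(r1$nes) == sign(r1$es), na.rm = TRUE))
  expect_true(all(r1$perm_p > 0 & r1$perm_p <= 1))
  # the pathway shifted down in the treatment group ranks on top
  expect_equal(r1$pathway[1], "pathway_02")
})

test_that("random member sets have mean |NES| near 1 under the null", {
  pw <- random_pathways(15, 300, size_range = c(10, 25), seed = 6)
  sim <- simulate_metabolome(300, pw, n_per_group = 4, seed = 7)
  ranked <- rank_features(sim$abundance, sim$groups)
  res <- normalize_permutation(ranked, pw, n_perm = 300, seed = 8)
  expect_lt(abs(mean(abs(res$nes)) - 1), 0.25)
})

test_that("undersized pathways are skipped with a warning", {
  r <- stats::setNames(rnorm(20), sprintf("f%04d", 1:20))
  pw <- list(ok = sprintf("f%04d", 1:5), gone = c("zzz1", "zzz2"))
  expect_warning(res <- normalize_permutation(r, pw, n_perm = 100,
                                              seed = 1),
                 "skipping pathway 'gone'")
  expect_equal(res$pathway, "ok")
})

test_that("PCA overview matches an eigendecomposition oracle", {
  set.seed(12)
  mat <- matrix(rnorm(12), 3, 4,
                dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  ov <- overview_pca(mat)
  z <- t(scale(t(mat)))
  ev <- eigen(stats::cov(t(z)))$values
  ve_oracle <- ev / sum(ev)
  expect_equal(ov$variance_explained[seq_along(ve_oracle)], ve_oracle,
               tolerance = 1e-10)
  expect_true(all(diff(ov$variance_explained) <= 1e-12))
  # row standardization
  expect_equal(unname(rowMeans(ov$zscores)), rep(0, 3))
  expect_equal(unname(apply(ov$zscores, 1, sd)), rep(1, 3))
})

test_that("collinear samples load entirely on the first component", {
  base <- rnorm(5)
  mat <- cbind(s1 = base, s2 = 2 * base, s3 = 3 * base, s4 = 4 * base)
  rownames(mat) <- paste0("f", 1:5)
  ov <- overview_pca(mat)
  expect_equal(ov$variance_explained[1], 1, tolerance = 1e-9)
})

test_that("constant features are dropped with a warning", {
  mat <- rbind(f1 = c(1, 2, 3, 4), f2 = rep(2, 4), f3 = c(4, 3, 2, 1))
  colnames(mat) <- paste0("s", 1:4)
  expect_warning(ov <- overview_pca(mat), "constant feature")
  expect_equal(nrow(ov$zscores), 2)
  expect_error(suppressWarnings(
    overview_pca(rbind(f1 = rep(1, 4), f2 = rep(2, 4)))),
    "non-constant")
})

test_that("pathway sets round-trip through GMT", {
  pw <- random_pathways(4, 50, seed = 9)
  path <- file.path(tempdir(), "sets.gmt")
  write_gmt(pw, path)
  back <- read_gmt(path)
  expect_equal(back[names(pw)], pw)
  unlink(path)
})
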