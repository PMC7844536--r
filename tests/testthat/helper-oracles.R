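# Independent oracles used across tests. These are deliberately naive,
# brute-force computations kept separate from the package internals.

# Kruskal-Wallis H (tie-corrected) and all-pairs Dunn z by direct rank
# arithmetic over a named list of samples.
brute_kruskal_dunn <- function(samples) {
  vals <- unlist(samples, use.names = FALSE)
  g <- rep(names(samples), lengths(samples))
  N <- length(vals)
  r <- rank(vals)
  Rj <- tapply(r, g, sum)
  nj <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(vals)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  rbar <- Rj / nj
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  labs <- names(samples)
  pairs <- utils::combn(length(labs), 2)
  z <- apply(pairs, 2, function(ij) {
    (rbar[labs[ij[1]]] - rbar[labs[ij[2]]]) /
      sqrt(v0 * (1 / nj[labs[ij[1]]] + 1 / nj[labs[ij[2]]]))
  })
  list(H = unname(H), z = unname(z),
       pair_labels = apply(pairs, 2, function(ij) {
         paste(labs[ij[1]], labs[ij[2]], sep = "|")
       }))
}

# GSEA running sum by explicit full walk over the ranked list.
brute_es <- function(scores, member_ids, weight = 1) {
  scores <- scores[order(-scores, names(scores))]
  is_hit <- names(scores) %in% member_ids
  N <- length(scores)
  k <- sum(is_hit)
  w <- abs(scores)^weight
  denom <- sum(w[is_hit])
  inc <- if (denom == 0) {
    ifelse(is_hit, 1 / k, 0)
  } else {
    ifelse(is_hit, w / denom, 0)
  }
  step <- ifelse(is_hit, inc, -1 / (N - k))
  path <- cumsum(step)
  hi <- max(path)
  lo <- min(path)
  # magnitude ties (up to float noise) resolve to the positive extreme
  if (hi + lo >= -1e-12) hi else lo
}

# Two-sided exact Mann-Whitney p by full enumeration (mirror of the
# package's definition, written independently with a sum-over-subsets of
# raw values rather than precomputed pooled ranks).
brute_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  u_of <- function(sel) {
    x <- pooled[sel]
    y <- pooled[-sel]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  us <- apply(idx, 2, u_of)
  u_obs <- u_of(seq_len(na))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Lognormal cohort helper for the comparison / epistasis simulations.
draw_lognormal_groups <- function(folds, n, sd_log) {
  lapply(folds, function(f) stats::rlnorm(n, log(f), sd_log))
}
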