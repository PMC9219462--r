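# Independent brute-force oracles used to cross-check the implementation.

# per-species SIMPER contributions by direct enumeration of between-group
# site pairs
oracle_simper <- function(x, groups, pair) {
  ia <- which(groups == pair[1])
  ib <- which(groups == pair[2])
  contrib <- matrix(0, length(ia) * length(ib), ncol(x))
  k <- 0
  for (i in ia) for (j in ib) {
    k <- k + 1
    denom <- sum(x[i, ] + x[j, ])
    contrib[k, ] <- abs(x[i, ] - x[j, ]) / denom
  }
  stats::setNames(colMeans(contrib), colnames(x))
}

# ANOSIM R from first principles (average ranks for ties)
oracle_anosim_R <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  pairs <- utils::combn(n, 2)
  vals <- dm[t(pairs)]
  rk <- rank(vals)
  within <- groups[pairs[1, ]] == groups[pairs[2, ]]
  m <- n * (n - 1) / 2
  (mean(rk[!within]) - mean(rk[within])) / (m / 2)
}

# exhaustive permutation p-values for ANOSIM on small n: `tied` counts
# relabelings matching the observed statistic (grouping-preserving ones
# always do), `strict` does not
oracle_anosim_p_exhaustive <- function(d, groups) {
  n <- length(groups)
  obs <- oracle_anosim_R(d, groups)
  perms <- permutations_all(n)
  rs <- apply(perms, 1, function(idx) oracle_anosim_R(d, groups[idx]))
  list(tied = mean(rs >= obs - 1e-12), strict = mean(rs > obs + 1e-12))
}

permutations_all <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_all(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      row <- row + 1
      out[row, ] <- append(sub[j, ] + (sub[j, ] >= i), i, after = i - 1)
    }
  }
  out
}

# expected richness in a subsample of m via full formula, written directly
oracle_rarefaction <- function(counts, m) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  sum(1 - exp(lchoose(n - counts, m) - lchoose(n, m)))
}

# random additive (tree-derived) distance matrix plus its source tree
random_additive_matrix <- function(n_leaves) {
  tr <- ape::rtree(n_leaves)
  list(tree = tr, d = stats::cophenetic(tr))
}

# small aligned DNAbin fixture from character strings
dnabin_from_strings <- function(strs, ids = paste0("t", seq_along(strs))) {
  mat <- do.call(rbind, strsplit(tolower(strs), ""))
  rownames(mat) <- ids
  ape::as.DNAbin(mat)
}

# one default synthetic bundle shared across tests (deterministic)
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- assemble_communities(scenario_config(seed = 42))
    cache
  }
})
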