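#' Fourth-root transform of an abundance matrix
#'
#' x -> x^(1/4), the standard severe down-weighting applied before
#' Bray-Curtis resemblance so that very abundant species do not swamp the
#' analysis. Monotone, fixes 0 and 1.
#'
#' @param cm a [community_matrix()] or non-negative matrix.
#' @return a plain numeric matrix of transformed abundances (labels kept).
#' @export
fourth_root_transform <- function(cm) {
  x <- as_abundance(cm)
  if (any(x < 0)) stop("fourth-root transform needs non-negative entries")
  x^0.25
}

#' Bray-Curtis dissimilarity between sites
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), in \[0, 1\]. A pair of
#' entirely empty sites is assigned distance 0 by convention (with a
#' warning).
#'
#' @param cm abundance (often fourth-root transformed) matrix with >= 2
#'   sites.
#' @return a `dist` of pairwise dissimilarities.
#' @export
bray_curtis <- function(cm) {
  x <- as_abundance(cm)
  if (nrow(x) < 2) stop("Bray-Curtis needs at least 2 sites")
  # empty sites are handled here (d = 1 against non-empty sites, 0 between
  # empty pairs), so vegdist's own empty-row warning is redundant
  d <- suppressWarnings(vegan::vegdist(x, method = "bray"))
  if (anyNA(d)) {
    warning("pair(s) of empty sites assigned Bray-Curtis distance 0")
    d[is.na(d)] <- 0
  }
  d
}

#' UPGMA (group-average) clustering of a dissimilarity matrix
#'
#' @param d a `dist` or symmetric matrix of dissimilarities.
#' @return an `hclust` dendrogram with non-decreasing merge heights.
#' @export
upgma_cluster <- function(d) {
  d <- stats::as.dist(d)
  if (attr(d, "Size") < 2) stop("clustering needs at least 2 sites")
  stats::hclust(d, method = "average")
}

#' Export a dendrogram as a Newick string
#'
#' @param hc an `hclust`, e.g. from [upgma_cluster()].
#' @return single-element character vector (Newick, with semicolon).
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Non-metric multidimensional scaling (NMDS)
#'
#' Kruskal's rank-based ordination minimizing stress-1,
#' sqrt(sum (d_ij - dhat_ij)^2 / sum d_ij^2), where dhat are monotone
#' (isotonic) regressed disparities. The best configuration over random
#' restarts is returned, centered at the origin.
#'
#' @param d `dist` (or symmetric matrix) of dissimilarities; must be finite.
#' @param k number of ordination axes, default 2.
#' @param n_restarts random restarts, default 50.
#' @param max_iter maximum iterations per restart.
#' @param seed RNG seed for reproducible restarts (optional).
#' @return an `nmds_result` list: `points` (n x k, centered), `stress`,
#'   `converged`, `n_restarts`, `seed`.
#' @export
nmds_ordination <- function(d, k = 2, n_restarts = 50, max_iter = 500,
                            seed = NULL) {
  d <- stats::as.dist(d)
  if (any(!is.finite(as.vector(d)))) stop("non-finite dissimilarities")
  if (k < 1) stop("k must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  fit <- suppressWarnings(vegan::metaMDS(d, k = k, try = n_restarts,
                                         trymax = n_restarts,
                                         autotransform = FALSE, trace = 0,
                                         maxit = max_iter, wascores = FALSE))
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  structure(list(points = pts, stress = fit$stress,
                 converged = as.numeric(fit$converged)[1L] > 0,
                 n_restarts = n_restarts, seed = seed),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d sites, %d axes, stress-1 = %.4f (%s, %d restarts)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "not converged",
              x$n_restarts))
  invisible(x)
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based contrast of between-group versus within-group dissimilarities:
#' R = (mean between-group rank - mean within-group rank) / (M / 2) with
#' M = n(n-1)/2, so R is in \[-1, 1\]. Significance is by random label
#' permutation with the (c + 1) / (n_perm + 1) estimator (one-sided, large
#' R).
#'
#' @param d `dist` (or symmetric matrix) of site dissimilarities.
#' @param groups grouping vector, one label per site; >= 2 groups, and no
#'   group may contain all sites.
#' @param n_permutations number of label permutations, default 999
#'   (minimum 99).
#' @param seed RNG seed (optional).
#' @return an `anosim_result` list: `R`, `p_value`, `n_permutations`,
#'   `seed`.
#' @export
anosim_test <- function(d, groups, n_permutations = 999, seed = NULL) {
  d <- stats::as.dist(d)
  groups <- as.factor(groups)
  n <- attr(d, "Size")
  if (length(groups) != n) stop("one group label per site is required")
  if (nlevels(droplevels(groups)) < 2) stop("ANOSIM needs at least 2 groups")
  if (max(table(groups)) == n) stop("a group contains all sites")
  if (n_permutations < 99) stop("use at least 99 permutations")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::anosim(d, groups, permutations = n_permutations)
  structure(list(R = unname(fit$statistic), p_value = fit$signif,
                 n_permutations = n_permutations, seed = seed),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, p = %.4f (%d permutations)\n",
              x$R, x$p_value, x$n_permutations))
  invisible(x)
}

#' SIMPER: species contributions to between-group dissimilarity
#'
#' For every between-group pair of sites, species i contributes
#' |x_i - y_i| / sum_j (x_j + y_j) to the pair's Bray-Curtis dissimilarity;
#' contributions are averaged over all between-group pairs. The per-species
#' averages sum exactly to the average between-group dissimilarity, and
#' contribution rates are the percentages of that total. Apply the same
#' transform (typically [fourth_root_transform()]) used for the Bray-Curtis
#' analysis before calling.
#'
#' @param cm abundance matrix (transformed or raw).
#' @param groups grouping vector, one label per site.
#' @param pair character vector of the two group labels to contrast;
#'   defaults to the first two levels.
#' @param percent if `TRUE` (default) scale contributions by 100, the
#'   conventional presentation.
#' @return a `simper_table` data frame sorted by contribution descending,
#'   with attribute `average_dissimilarity`.
#' @export
simper_table <- function(cm, groups, pair = NULL, percent = TRUE) {
  x <- as_abundance(cm)
  groups <- as.factor(groups)
  if (length(groups) != nrow(x)) stop("one group label per site is required")
  if (is.null(pair)) pair <- levels(droplevels(groups))[1:2]
  if (length(pair) != 2 || anyNA(pair) || pair[1] == pair[2])
    stop("'pair' must name two distinct groups")
  if (!all(pair %in% groups)) stop("both groups must be non-empty")
  keep <- groups %in% pair
  xs <- x[keep, , drop = FALSE]
  g <- droplevels(factor(groups[keep], levels = pair))
  sim <- vegan::simper(xs, g, permutations = 0)
  avg <- sim[[1L]]$average
  scale <- if (percent) 100 else 1
  total <- sum(avg)
  out <- data.frame(species = names(avg),
                    average_dissimilarity = scale * avg,
                    contribution_pct = 100 * avg / total)
  out <- out[order(-out$average_dissimilarity), ]
  out$cumulative_pct <- cumsum(out$contribution_pct)
  rownames(out) <- NULL
  attr(out, "average_dissimilarity") <- scale * total
  attr(out, "groups") <- pair
  class(out) <- c("simper_table", "data.frame")
  out
}
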