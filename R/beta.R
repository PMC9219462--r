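#' Pairwise beta-diversity partition (Sorensen family)
#'
#' For two presence/absence vectors on a common species list with a shared
#' species, b and c species exclusive to each site:
#' beta_sor = (b + c) / (2a + b + c) (total dissimilarity),
#' beta_sim = min(b, c) / (a + min(b, c)) (spatial turnover), and
#' beta_sne = beta_sor - beta_sim (nestedness-resultant component). The
#' three satisfy beta_sor = beta_sim + beta_sne exactly.
#'
#' @param x,y presence/absence (or abundance; any positive value counts as
#'   presence) vectors over the same species.
#' @return a `beta_partition` list with `beta_sor`, `beta_sim`, `beta_sne`,
#'   `mode = "pairwise"`.
#' @export
beta_pair <- function(x, y) {
  if (length(x) != length(y))
    stop("incidence vectors must share a common species list")
  px <- x > 0
  py <- y > 0
  if (!any(px) && !any(py)) stop("both sites are empty")
  a <- sum(px & py)
  b <- sum(px & !py)
  c <- sum(!px & py)
  bsor <- (b + c) / (2 * a + b + c)
  bsim <- if (a + min(b, c) == 0) 0 else min(b, c) / (a + min(b, c))
  new_beta_partition(bsor, bsim, bsor - bsim, "pairwise")
}

new_beta_partition <- function(bsor, bsim, bsne, mode) {
  structure(list(beta_sor = bsor, beta_sim = bsim, beta_sne = bsne,
                 mode = mode),
            class = "beta_partition")
}

#' @export
print.beta_partition <- function(x, ...) {
  cat(sprintf("beta partition (%s): beta_sor = %.4f = beta_sim %.4f + beta_sne %.4f\n",
              x$mode, x$beta_sor, x$beta_sim, x$beta_sne))
  invisible(x)
}

# drop species never observed and complain about empty sites
incidence_for_beta <- function(cm) {
  x <- as_abundance(cm) > 0
  x <- x[, colSums(x) > 0, drop = FALSE]
  if (nrow(x) < 2) stop("beta diversity needs at least 2 sites")
  if (any(rowSums(x) == 0)) stop("beta diversity needs non-empty sites")
  x
}

#' Mean pairwise beta-diversity partition over all site pairs
#'
#' Arithmetic mean of each pairwise component over all unordered site pairs.
#' Species never observed in the matrix are dropped first.
#'
#' @param cm a [community_matrix()] (or matrix) with >= 2 non-empty sites.
#' @return a `beta_partition` with `mode = "pairwise-mean"`.
#' @export
beta_mean_pairwise <- function(cm) {
  x <- incidence_for_beta(cm)
  n <- nrow(x)
  pairs <- utils::combn(n, 2)
  parts <- apply(pairs, 2, function(ij) {
    p <- beta_pair(x[ij[1L], ], x[ij[2L], ])
    c(p$beta_sor, p$beta_sim, p$beta_sne)
  })
  m <- rowMeans(parts)
  new_beta_partition(m[1L], m[2L], m[3L], "pairwise-mean")
}

#' Multiple-site beta-diversity partition
#'
#' Baselga's multiple-site generalization. With S_i the richness of site i,
#' S_T the pooled richness, and b_ij, b_ji the numbers of species exclusive
#' to sites i and j when compared pairwise:
#' beta_SIM = sum min(b_ij, b_ji) / (A + sum min),
#' beta_SOR = (sum min + sum max) / (2A + sum min + sum max), where
#' A = sum S_i - S_T, and beta_SNE = beta_SOR - beta_SIM.
#' Values are invariant to site order and reduce to the pairwise formulas
#' for two sites.
#'
#' @inheritParams beta_mean_pairwise
#' @return a `beta_partition` with `mode = "multisite"`.
#' @export
beta_multisite <- function(cm) {
  x <- incidence_for_beta(cm)
  n <- nrow(x)
  a_tot <- sum(rowSums(x)) - sum(colSums(x) > 0)
  smin <- 0
  smax <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      bij <- sum(x[i, ] & !x[j, ])
      bji <- sum(!x[i, ] & x[j, ])
      smin <- smin + min(bij, bji)
      smax <- smax + max(bij, bji)
    }
  }
  bsim <- if (a_tot + smin == 0) 0 else smin / (a_tot + smin)
  bsor <- (smin + smax) / (2 * a_tot + smin + smax)
  new_beta_partition(bsor, bsim, bsor - bsim, "multisite")
}

#' Temporal homogenization contrast
#'
#' Difference of the Sorensen dissimilarity between an earlier and a later
#' survey, delta = beta_sor(A) - beta_sor(B). With A the earlier year,
#' delta > 0 means among-site compositional dissimilarity declined over
#' time, i.e. biotic homogenization; delta < 0 indicates differentiation.
#' The exact difference of the inputs is returned without rounding.
#'
#' @param beta_a,beta_b `beta_partition` objects of the same mode; `beta_a`
#'   is the earlier survey.
#' @return list with `delta_beta_sor` and `direction` in
#'   `c("homogenization", "differentiation", "none")`.
#' @export
homogenization <- function(beta_a, beta_b) {
  stopifnot(inherits(beta_a, "beta_partition"), inherits(beta_b, "beta_partition"))
  if (!identical(beta_a$mode, beta_b$mode))
    stop("beta partitions must share the same mode (got '", beta_a$mode,
         "' and '", beta_b$mode, "')")
  delta <- beta_a$beta_sor - beta_b$beta_sor
  direction <- if (delta > 0) "homogenization" else if (delta < 0) "differentiation" else "none"
  structure(list(delta_beta_sor = delta, direction = direction,
                 mode = beta_a$mode),
            class = "homogenization_report")
}

#' @export
print.homogenization_report <- function(x, ...) {
  cat(sprintf("delta beta_sor (%s) = %.4f -> %s\n",
              x$mode, x$delta_beta_sor, x$direction))
  invisible(x)
}

#' Pairwise Sorensen dissimilarity matrix
#'
#' Site-by-site beta_sor values, useful for inspecting which site pairs
#' drive the mean partition.
#'
#' @inheritParams beta_mean_pairwise
#' @return a `dist` of pairwise beta_sor values.
#' @export
beta_sor_matrix <- function(cm) {
  x <- incidence_for_beta(cm)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- beta_pair(x[i, ], x[j, ])$beta_sor
    }
  }
  stats::as.dist(d)
}
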