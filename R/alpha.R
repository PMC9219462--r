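#' Relative abundance of each species
#'
#' p_i = N_i / sum_j N_j. The returned vector sums to one exactly (within
#' floating tolerance).
#'
#' @param counts non-negative abundance vector with at least one positive
#'   entry.
#' @return probability vector of the same length (and names).
#' @export
relative_abundance <- function(counts) {
  if (any(counts < 0)) stop("abundances must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("all-zero abundance vector")
  counts / total
}

#' Shannon-Wiener diversity index
#'
#' H = -sum p_i ln p_i in natural-log units (nats); zero entries are skipped.
#'
#' @param p probability vector (non-negative, summing to one).
#' @return H >= 0.
#' @export
shannon_index <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6)
    stop("input must be a probability vector summing to 1; see relative_abundance()")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Margalef richness index
#'
#' D = (S - 1) / ln N.
#'
#' @param s species richness, >= 1.
#' @param n total number of individuals, >= 2 (the index degenerates at
#'   ln N = 0).
#' @return D >= 0.
#' @export
margalef_index <- function(s, n) {
  if (s < 1) stop("richness must be at least 1")
  if (n < 2) stop("Margalef index needs at least 2 individuals")
  (s - 1) / log(n)
}

#' Gini-Simpson index
#'
#' F = 1 - sum p_i^2, the probability that two randomly drawn individuals
#' belong to different species. Often printed as a "Simpson dominance index"
#' in survey reports even though larger values mean less dominance; the
#' formula here is the diversity form as printed.
#'
#' @param p probability vector.
#' @return F in \[0, 1).
#' @export
gini_simpson <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6)
    stop("input must be a probability vector summing to 1")
  1 - sum(p^2)
}

#' Pielou evenness index
#'
#' J = H / ln S, in \[0, 1\] for S >= 2. Undefined for a single species
#' (returned as `NA` with a warning).
#'
#' @param h Shannon index (nats).
#' @param s species richness.
#' @return J, or `NA` when S < 2.
#' @export
pielou_evenness <- function(h, s) {
  if (h < 0) stop("Shannon index must be non-negative")
  if (s < 2) {
    warning("Pielou evenness undefined for fewer than 2 species")
    return(NA_real_)
  }
  h / log(s)
}

#' All alpha-diversity indices for one community
#'
#' @param counts non-negative abundance vector.
#' @return one-row data frame with richness `S`, abundance `N`, Shannon `H`,
#'   Margalef `D`, Gini-Simpson `F`, and Pielou `J` (`NA` when S < 2; `D` is
#'   `NA` when N < 2).
#' @export
alpha_indices <- function(counts) {
  s <- sum(counts > 0)
  n <- sum(counts)
  if (s < 1) stop("community has no individuals")
  p <- relative_abundance(counts)
  h <- shannon_index(p)
  data.frame(S = s, N = n, H = h,
             D = if (n >= 2) margalef_index(s, n) else NA_real_,
             F = gini_simpson(p),
             J = if (s >= 2) h / log(s) else NA_real_)
}

#' Alpha diversity per site or pooled across sites
#'
#' Per-site indices are computed on each row of the matrix; pooled indices
#' on the column sums (all sites treated as one sample), the convention used
#' for reserve-level summaries.
#'
#' @param cm a [community_matrix()] of counts.
#' @param pooled if `TRUE` return the single pooled row.
#' @return data frame of indices, one row per site (plus row names) or one
#'   pooled row.
#' @export
alpha_table <- function(cm, pooled = FALSE) {
  x <- as_abundance(cm)
  if (pooled) {
    out <- alpha_indices(colSums(x))
    rownames(out) <- "pooled"
    return(out)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
    row <- x[i, ]
    if (sum(row) == 0) {
      data.frame(S = 0L, N = 0, H = NA_real_, D = NA_real_,
                 F = NA_real_, J = NA_real_)
    } else {
      suppressWarnings(alpha_indices(row))
    }
  }))
  rownames(out) <- rownames(x)
  out
}

#' Index of relative importance (IRI) dominance table
#'
#' IRI_i = (%N_i + %W_i) x f_i, with %N and %W the percentages of total
#' individuals and total weight on the 0-100 scale and f_i the fraction of
#' sites at which species i occurs (0-1), so the maximum attainable IRI is
#' 200. Species are ranked by IRI descending; those at or above
#' `dominant_threshold` are flagged dominant (no published cutoff exists for
#' this scaling, so the threshold is configurable).
#'
#' @param counts count-kind [community_matrix()].
#' @param biomass biomass-kind [community_matrix()] on the same sites and
#'   species.
#' @param dominant_threshold IRI value at or above which a species is called
#'   dominant; default 10.
#' @return data frame with `species`, `pct_n`, `pct_w`, `f`, `iri`,
#'   `dominant`, sorted by `iri` descending.
#' @export
iri_table <- function(counts, biomass, dominant_threshold = 10) {
  xc <- as_abundance(counts)
  xw <- as_abundance(biomass)
  miss <- setdiff(colnames(xc), colnames(xw))
  if (length(miss))
    stop("species present in counts but absent in biomass: ",
         paste(miss, collapse = ", "))
  if (!identical(rownames(xc), rownames(xw)))
    stop("count and biomass matrices must share the same sites")
  xw <- xw[, colnames(xc), drop = FALSE]
  n <- colSums(xc)
  w <- colSums(xw)
  if (sum(n) == 0 || sum(w) == 0) stop("empty survey")
  out <- data.frame(species = colnames(xc),
                    pct_n = 100 * n / sum(n),
                    pct_w = 100 * w / sum(w),
                    f = colMeans(xc > 0))
  out$iri <- (out$pct_n + out$pct_w) * out$f
  out$dominant <- out$iri >= dominant_threshold
  out <- out[order(-out$iri), ]
  rownames(out) <- NULL
  out
}

#' Chao1 richness estimate and sampling completeness
#'
#' Classical Chao1: S_obs + f1^2 / (2 f2) when doubletons exist, otherwise
#' the bias-corrected fallback S_obs + f1 (f1 - 1) / 2. Completeness is
#' S_obs / Chao1.
#'
#' @param counts integer abundance vector (pooled species counts).
#' @return list with `s_obs`, `f1`, `f2`, `chao1`, `completeness`.
#' @export
chao1_estimate <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("Chao1 needs non-negative integer counts")
  counts <- counts[counts > 0]
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  chao1 <- if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
  list(s_obs = s_obs, f1 = f1, f2 = f2, chao1 = chao1,
       completeness = s_obs / chao1)
}

#' Abundance-based rarefaction curve
#'
#' Expected richness in a random subsample of m individuals,
#' E\[S_m\] = sum_i (1 - C(N - N_i, m) / C(N, m)); non-decreasing in m and
#' equal to the observed richness at m = N. Subsample sizes beyond N
#' (extrapolation) are not supported.
#'
#' @param counts integer abundance vector.
#' @param m subsample sizes, 1 <= m <= sum(counts); default an even grid of
#'   up to 50 sizes ending at N.
#' @return data frame with columns `m` and `expected_richness`.
#' @export
rarefaction_curve <- function(counts, m = NULL) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("rarefaction needs non-negative integer counts")
  n <- sum(counts)
  if (n < 1) stop("empty community")
  if (is.null(m)) m <- unique(round(seq(1, n, length.out = min(50, n))))
  if (any(m < 1) || any(m > n))
    stop("subsample sizes must lie in [1, N]; extrapolation is not supported")
  es <- as.numeric(suppressWarnings(vegan::rarefy(counts, sample = m)))
  data.frame(m = m, expected_richness = es)
}

#' Sampling-completeness report
#'
#' Combines the Chao1 estimate with a rarefaction curve for a pooled survey.
#'
#' @inheritParams rarefaction_curve
#' @return list with the [chao1_estimate()] fields plus `rarefaction`.
#' @export
completeness_report <- function(counts, m = NULL) {
  est <- chao1_estimate(counts)
  est$rarefaction <- rarefaction_curve(counts, m)
  est
}
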