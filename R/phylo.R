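#' Read an aligned FASTA file
#'
#' Sequences must be aligned (equal length) with unique identifiers matching
#' the species labels of the community matrices they will be paired with.
#' Case is normalized internally.
#'
#' @param path FASTA file of aligned DNA sequences.
#' @return a `DNAbin` matrix (taxa x alignment columns).
#' @export
read_fasta <- function(path) {
  seqs <- ape::read.FASTA(path)
  if (length(seqs) < 1) stop("no sequences found in ", path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id: ", names(seqs)[duplicated(names(seqs))][1L])
  len <- lengths(seqs)
  if (length(unique(len)) > 1)
    stop("unequal alignment length (", paste(sort(unique(len)), collapse = ", "),
         "); sequences must be aligned")
  as.matrix(seqs)
}

check_dnabin <- function(seqs) {
  if (!inherits(seqs, "DNAbin")) stop("expected a DNAbin alignment")
  as.matrix(seqs)
}

finite_or_stop <- function(d, what) {
  if (any(!is.finite(as.vector(d))))
    stop(what, ": saturated or non-comparable sequence pair ",
         "(check divergence and shared non-gap sites)")
  d
}

#' Uncorrected p-distance between aligned sequences
#'
#' Proportion of differing sites among the sites comparable for each pair;
#' sites with a gap or ambiguity in either sequence are excluded pairwise.
#'
#' @param seqs `DNAbin` alignment, e.g. from [read_fasta()].
#' @return a `dist` of pairwise distances.
#' @export
p_distance <- function(seqs) {
  x <- check_dnabin(seqs)
  d <- ape::dist.dna(x, model = "raw", pairwise.deletion = TRUE)
  finite_or_stop(d, "p-distance")
}

#' Kimura two-parameter (K2P) distance
#'
#' d = (1/2) ln(1 / (1 - 2P - Q)) + (1/4) ln(1 / (1 - 2Q)) with P and Q the
#' proportions of transition (A<->G, C<->T) and transversion differences.
#' Gap/ambiguous sites are excluded pairwise. Saturated pairs (the log
#' arguments non-positive) are an error.
#'
#' @inheritParams p_distance
#' @return a `dist` of pairwise distances (substitutions/site).
#' @export
k2p_distance <- function(seqs) {
  x <- check_dnabin(seqs)
  d <- ape::dist.dna(x, model = "K80", pairwise.deletion = TRUE)
  finite_or_stop(d, "K2P distance")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: iteratively join the pair minimizing
#' Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k), with branch
#' lengths from the canonical split formula. Exact on additive matrices.
#' Negative estimated branch lengths are clamped to zero with a warning.
#'
#' @param d symmetric non-negative distance matrix or `dist` over >= 3 taxa.
#' @return an unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(stats::as.dist(d))
  if (nrow(m) < 3) stop("neighbor-joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(m))
  if (any(tr$edge.length < 0)) {
    warning("negative neighbor-joining branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Cophenetic (path-length) distances between the leaves of a tree
#'
#' @param tree a `phylo` tree with branch lengths.
#' @return symmetric matrix of patristic distances, labeled by tip.
#' @export
cophenetic_distances <- function(tree) {
  if (!inherits(tree, "phylo")) stop("expected a phylo tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  stats::cophenetic(tree)
}

#' Observed mean pairwise phylogenetic distance (MPD)
#'
#' Unweighted mean of the distances between all unordered pairs of species
#' present in the community. Undefined (returned `NA` with a warning) for
#' fewer than two species.
#'
#' @param species character vector of species present, or a named
#'   incidence/abundance vector (positive entries mark presence).
#' @param d species distance matrix (e.g. [cophenetic_distances()]) whose
#'   labels cover the species.
#' @return MPD, or `NA` for a sub-2-species community.
#' @export
mpd_observed <- function(species, d) {
  if (!is.character(species)) {
    if (is.null(names(species))) stop("incidence vector must be named by species")
    species <- names(species)[species > 0]
  }
  if (length(species) < 2) {
    warning("MPD undefined for fewer than 2 species")
    return(NA_real_)
  }
  miss <- setdiff(species, rownames(d))
  if (length(miss))
    stop("species missing from the distance matrix: ",
         paste(miss, collapse = ", "))
  sub <- d[species, species]
  mean(sub[upper.tri(sub)])
}

#' Null distribution of MPD under richness-preserving randomization
#'
#' Draws `n_rand` communities of the given richness uniformly without
#' replacement from the species pool (equivalent in distribution to
#' shuffling taxa labels across the tree) and records each draw's MPD. The
#' summary SD is the population (divide-by-n) form.
#'
#' @param richness number of species per randomized community (>= 2, and at
#'   most the pool size).
#' @param pool_d distance matrix over the species pool.
#' @param n_rand number of randomizations, default 999.
#' @param seed RNG seed (optional).
#' @return a `null_mpd` list: `values`, `mean`, `sd`, `n_rand`, `richness`,
#'   `seed`.
#' @export
null_mpd <- function(richness, pool_d, n_rand = 999, seed = NULL) {
  pool_d <- as.matrix(pool_d)
  np <- nrow(pool_d)
  if (richness > np) stop("community richness exceeds the species pool")
  if (richness < 2) stop("null MPD needs richness of at least 2")
  if (!is.null(seed)) set.seed(seed)
  vals <- vapply(seq_len(n_rand), function(i) {
    idx <- sample.int(np, richness)
    sub <- pool_d[idx, idx]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  m <- mean(vals)
  s <- sqrt(mean((vals - m)^2))
  structure(list(values = vals, mean = m, sd = s, n_rand = n_rand,
                 richness = richness, seed = seed),
            class = "null_mpd")
}

#' Net relatedness index (NRI)
#'
#' NRI = (mean(MPD_null) - MPD_obs) / SD(MPD_null): positive values mean
#' the observed community is phylogenetically clustered relative to the
#' null (co-occurring species closer than expected), negative values mean
#' overdispersion. Undefined when the null SD is zero.
#'
#' @param mpd_obs observed MPD.
#' @param null a [null_mpd()] object, or the null mean (then supply
#'   `null_sd`).
#' @param null_sd null standard deviation when `null` is given as a number.
#' @return the NRI value, or `NA` with a warning when undefined.
#' @export
nri <- function(mpd_obs, null, null_sd = NULL) {
  if (inherits(null, "null_mpd")) {
    m <- null$mean
    s <- null$sd
  } else {
    m <- null
    s <- null_sd
  }
  if (is.na(mpd_obs)) return(NA_real_)
  if (is.null(s) || is.na(s) || s <= 0) {
    warning("null SD is zero; NRI undefined")
    return(NA_real_)
  }
  (m - mpd_obs) / s
}

#' Assembly-mechanism call from the sign of NRI
#'
#' @param nri_value NRI value(s).
#' @return `"environmental_filtering"` for NRI > 0, `"competition"` for
#'   NRI < 0, `"indeterminate"` for 0 or `NA`.
#' @export
assembly_call <- function(nri_value) {
  out <- rep("indeterminate", length(nri_value))
  out[!is.na(nri_value) & nri_value > 0] <- "environmental_filtering"
  out[!is.na(nri_value) & nri_value < 0] <- "competition"
  out
}

#' Per-community NRI table
#'
#' For each site (row) of the community matrix: observed MPD of the species
#' present, a richness-preserving null distribution drawn from the species
#' pool, the null mean and SD, NRI, and the assembly call. The pool
#' defaults to every species observed in the matrix (the survey-wide pool);
#' supply `pool` explicitly to test against a larger pool (e.g. the union
#' of several surveys). Sites with fewer than two species get an `NA` row.
#'
#' @param cm a [community_matrix()].
#' @param phy a `phylo` tree or a species distance matrix covering the
#'   pool.
#' @param n_rand randomizations per community, default 999.
#' @param seed master seed; per-site sub-seeds are drawn from it so the
#'   table is reproducible as a whole.
#' @param pool character vector of pool species (default: species with
#'   positive total abundance in `cm`).
#' @return data frame with one row per site: `site`, `richness`,
#'   `mpd_null_mean`, `mpd_obs`, `sd_null`, `nri`, `assembly`.
#' @export
nri_table <- function(cm, phy, n_rand = 999, seed = NULL, pool = NULL) {
  x <- as_abundance(cm)
  d <- if (inherits(phy, "phylo")) cophenetic_distances(phy) else as.matrix(phy)
  if (is.null(pool)) pool <- colnames(x)[colSums(x) > 0]
  miss <- setdiff(pool, rownames(d))
  if (length(miss))
    stop("pool species missing from the tree/distance matrix: ",
         paste(miss, collapse = ", "))
  dp <- d[pool, pool]
  if (!is.null(seed)) set.seed(seed)
  site_seeds <- sample.int(.Machine$integer.max, nrow(x))
  rows <- lapply(seq_len(nrow(x)), function(i) {
    present <- intersect(colnames(x)[x[i, ] > 0], pool)
    r <- length(present)
    if (r < 2) {
      return(data.frame(site = rownames(x)[i], richness = r,
                        mpd_null_mean = NA_real_, mpd_obs = NA_real_,
                        sd_null = NA_real_, nri = NA_real_,
                        assembly = "indeterminate"))
    }
    obs <- mpd_observed(present, dp)
    if (r == length(pool)) {
      # degenerate: every draw equals the observed community
      return(data.frame(site = rownames(x)[i], richness = r,
                        mpd_null_mean = obs, mpd_obs = obs,
                        sd_null = 0, nri = NA_real_,
                        assembly = "indeterminate"))
    }
    nd <- null_mpd(r, dp, n_rand = n_rand, seed = site_seeds[i])
    z <- nri(obs, nd)
    data.frame(site = rownames(x)[i], richness = r,
               mpd_null_mean = nd$mean, mpd_obs = obs, sd_null = nd$sd,
               nri = z, assembly = assembly_call(z))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
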