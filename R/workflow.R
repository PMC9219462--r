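#' Run the full two-survey diversity analysis
#'
#' Orchestrates every stage on a pair of surveys sharing a species naming
#' scheme and a phylogeny: per-site and pooled alpha diversity, IRI
#' dominance (when biomass is available), Chao1 completeness, mean-pairwise
#' and multiple-site beta-diversity partitions with the temporal
#' homogenization contrast, fourth-root Bray-Curtis / UPGMA / NMDS / ANOSIM
#' / SIMPER per survey, per-community NRI tables against each survey's own
#' species pool plus a reserve-total row against the union pool, and the
#' species turnover report. All stochastic stages draw their sub-seeds from
#' the single master seed, so the whole report is reproducible from its
#' manifest.
#'
#' @param x a `synthetic_bundle` from [assemble_communities()], or a
#'   count-kind [community_matrix()] for the earlier survey (then supply
#'   `counts_b` and `tree`).
#' @param counts_b later-survey counts (ignored for bundles).
#' @param tree `phylo` covering every species observed in either survey
#'   (ignored for bundles, which carry their own).
#' @param biomass_a,biomass_b optional biomass matrices for IRI.
#' @param groups_a,groups_b optional site-group labels for ANOSIM/SIMPER;
#'   by default sites are grouped by cutting the UPGMA dendrogram into
#'   `n_groups` clusters.
#' @param n_groups number of dendrogram-derived groups, default 3.
#' @param n_rand null-model randomizations per community, default 999.
#' @param n_permutations ANOSIM permutations, default 999.
#' @param nmds_restarts NMDS random restarts, default 20.
#' @param k NMDS dimensions, default 2.
#' @param seed master seed, default 1.
#' @return a `diversity_report` list; see Details for components.
#' @details Components: `alpha` (per-site and pooled tables per survey),
#'   `iri`, `completeness`, `beta` (both partition modes per survey),
#'   `homogenization` (mean-pairwise and multisite), `turnover`,
#'   `assemblage` (per survey: `bray`, `upgma`, `nmds`, `groups`, `anosim`,
#'   `simper`), `nri` (per survey plus `total`), and `manifest`.
#' @export
run_full_analysis <- function(x, counts_b = NULL, tree = NULL,
                              biomass_a = NULL, biomass_b = NULL,
                              groups_a = NULL, groups_b = NULL, n_groups = 3,
                              n_rand = 999, n_permutations = 999,
                              nmds_restarts = 20, k = 2, seed = 1) {
  if (inherits(x, "synthetic_bundle")) {
    counts_a <- x$counts_a
    counts_b <- x$counts_b
    tree <- x$tree
    biomass_a <- x$biomass_a
    biomass_b <- x$biomass_b
  } else {
    counts_a <- x
    if (is.null(counts_b) || is.null(tree))
      stop("supply counts_b and tree, or a synthetic_bundle")
  }
  sp_a <- colnames(counts_a)[colSums(as_abundance(counts_a)) > 0]
  sp_b <- colnames(counts_b)[colSums(as_abundance(counts_b)) > 0]
  miss <- setdiff(union(sp_a, sp_b), tree$tip.label)
  if (length(miss))
    stop("species missing from the phylogeny: ", paste(miss, collapse = ", "))

  set.seed(seed)
  stage_seed <- as.list(sample.int(.Machine$integer.max, 6))
  names(stage_seed) <- c("nmds_a", "nmds_b", "anosim_a", "anosim_b",
                         "nri_a", "nri_b")

  analyse_year <- function(counts, groups, nmds_seed, anosim_seed) {
    x4 <- fourth_root_transform(counts)
    bray <- bray_curtis(x4)
    hc <- upgma_cluster(bray)
    if (is.null(groups)) {
      groups <- factor(stats::cutree(hc, k = min(n_groups, nrow(x4))))
    }
    groups <- as.factor(groups)
    nm <- nmds_ordination(bray, k = k, n_restarts = nmds_restarts,
                          seed = nmds_seed)
    an <- sim <- NULL
    if (nlevels(droplevels(groups)) >= 2 &&
        max(table(groups)) < length(groups)) {
      an <- anosim_test(bray, groups, n_permutations = n_permutations,
                        seed = anosim_seed)
      big <- names(sort(table(groups), decreasing = TRUE))[1:2]
      sim <- simper_table(x4, groups, pair = big)
    }
    list(transformed = x4, bray = bray, upgma = hc, groups = groups,
         nmds = nm, anosim = an, simper = sim)
  }

  d_full <- cophenetic_distances(tree)
  nri_year <- function(counts, pool, nri_seed) {
    nri_table(counts, d_full, n_rand = n_rand, seed = nri_seed, pool = pool)
  }
  # reserve-total communities are tested against the union pool of both
  # surveys; per-river rows use the survey's own pool
  pool_union <- union(sp_a, sp_b)
  total_row <- function(counts, label, nri_seed) {
    pooled <- matrix(colSums(as_abundance(counts)), 1,
                     dimnames = list(label, colnames(counts)))
    nri_table(community_matrix(pooled, kind = cm_kind(counts)), d_full,
              n_rand = n_rand, seed = nri_seed, pool = pool_union)
  }

  report <- list(
    alpha = list(
      per_site_a = alpha_table(counts_a), per_site_b = alpha_table(counts_b),
      pooled_a = alpha_table(counts_a, pooled = TRUE),
      pooled_b = alpha_table(counts_b, pooled = TRUE)),
    iri = if (!is.null(biomass_a) && !is.null(biomass_b))
      list(a = iri_table(counts_a, biomass_a),
           b = iri_table(counts_b, biomass_b)),
    completeness = list(
      a = completeness_report(round(colSums(as_abundance(counts_a)))),
      b = completeness_report(round(colSums(as_abundance(counts_b))))),
    beta = list(
      pairwise_a = beta_mean_pairwise(counts_a),
      pairwise_b = beta_mean_pairwise(counts_b),
      multisite_a = beta_multisite(counts_a),
      multisite_b = beta_multisite(counts_b)),
    turnover = compare_species_lists(counts_a, counts_b))
  report$homogenization <- list(
    pairwise = homogenization(report$beta$pairwise_a, report$beta$pairwise_b),
    multisite = homogenization(report$beta$multisite_a, report$beta$multisite_b))
  report$assemblage <- list(
    a = analyse_year(counts_a, groups_a, stage_seed$nmds_a, stage_seed$anosim_a),
    b = analyse_year(counts_b, groups_b, stage_seed$nmds_b, stage_seed$anosim_b))
  report$nri <- list(
    a = nri_year(counts_a, sp_a, stage_seed$nri_a),
    b = nri_year(counts_b, sp_b, stage_seed$nri_b),
    total = rbind(total_row(counts_a, "total_a", stage_seed$nri_a),
                  total_row(counts_b, "total_b", stage_seed$nri_b)))
  report$manifest <- list(
    package_version = as.character(utils::packageVersion("riverdiv")),
    seed = seed, stage_seeds = stage_seed,
    n_rand = n_rand, n_permutations = n_permutations,
    nmds_restarts = nmds_restarts, nmds_k = k, n_groups = n_groups,
    years = c(cm_year(counts_a), cm_year(counts_b)),
    n_sites = c(nrow(counts_a), nrow(counts_b)),
    richness = c(length(sp_a), length(sp_b)))
  class(report) <- "diversity_report"
  report
}

#' @export
print.diversity_report <- function(x, ...) {
  m <- x$manifest
  fmt2 <- function(v) formatC(v, format = "f", digits = 2)
  cat(sprintf("diversity report (seed %s): surveys %s vs %s\n",
              m$seed, m$years[1], m$years[2]))
  cat(sprintf("  richness %d -> %d (%d lost, %d gained)\n",
              m$richness[1], m$richness[2],
              length(x$turnover$lost), length(x$turnover$gained)))
  cat(sprintf("  pooled H %s -> %s, J %s -> %s\n",
              fmt2(x$alpha$pooled_a$H), fmt2(x$alpha$pooled_b$H),
              fmt2(x$alpha$pooled_a$J), fmt2(x$alpha$pooled_b$J)))
  cat(sprintf("  mean-pairwise beta_sor %s -> %s (delta %s, %s)\n",
              fmt2(x$beta$pairwise_a$beta_sor),
              fmt2(x$beta$pairwise_b$beta_sor),
              fmt2(x$homogenization$pairwise$delta_beta_sor),
              x$homogenization$pairwise$direction))
  if (!is.null(x$assemblage$a$anosim))
    cat(sprintf("  ANOSIM R: %s (A), %s (B)\n",
                fmt2(x$assemblage$a$anosim$R), fmt2(x$assemblage$b$anosim$R)))
  nt <- x$nri$total
  cat(sprintf("  total NRI: %s (A), %s (B)\n",
              fmt2(nt$nri[1]), fmt2(nt$nri[2])))
  invisible(x)
}
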