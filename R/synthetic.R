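#' Scenario configuration for the synthetic survey generator
#'
#' Defaults emulate the structure of a two-survey comparison of a small
#' stream network: 13 sites, a 17-species pool in the first survey with
#' strong dominance (a handful of species carrying most individuals),
#' turnover-dominated beta diversity along an environmental gradient,
#' 5 species lost and 4 gained between surveys, and a decline in evenness
#' and among-site dissimilarity in the later survey.
#'
#' @param n_sites number of sampling sites, default 13.
#' @param pool_size species pool of the first survey, default 17.
#' @param dominance_shape lognormal sigma of the rank-abundance
#'   distribution; larger values concentrate individuals in fewer species.
#' @param niche_breadth Gaussian niche breadth of species along the 0-1
#'   environmental gradient, default 0.25.
#' @param richness_mean mean per-site richness (Poisson, floored at 2).
#' @param site_total expected individuals per site, default 100.
#' @param assembly community-assembly mechanism: `"neutral"` (niche match
#'   only), `"filtering"` (co-occurring species drawn from a focal clade),
#'   or `"competition"` (close relatives of residents penalized).
#' @param filtering_strength strength of the filtering/competition effect
#'   in \[0, 1\], default 0.8.
#' @param species_lost,species_gained species dropped from / added to the
#'   pool in the later survey (defaults 5 and 4).
#' @param evenness_shift exponent boost (> 0) applied to relative
#'   abundances in the later survey to reduce evenness, default 0.5.
#' @param breadth_inflation niche-breadth multiplier in the later survey,
#'   default 1.35.
#' @param generalist_boost exponent tilting later-survey site membership
#'   toward globally abundant species (generalist expansion, the mechanism
#'   that homogenizes composition among sites), default 0.5.
#' @param sequence_length alignment length for simulated sequences,
#'   default 1071.
#' @param kappa transition:transversion ratio of the substitution process.
#' @param year_a,year_b survey-year labels.
#' @param seed master RNG seed; the whole bundle is a pure function of the
#'   configuration.
#' @return a validated `scenario_config` list.
#' @export
scenario_config <- function(n_sites = 13, pool_size = 17,
                            dominance_shape = 1.8, niche_breadth = 0.25,
                            richness_mean = 7, site_total = 100,
                            assembly = c("neutral", "filtering", "competition"),
                            filtering_strength = 0.8,
                            species_lost = 5, species_gained = 4,
                            evenness_shift = 0.5, breadth_inflation = 1.35,
                            generalist_boost = 0.5,
                            sequence_length = 1071, kappa = 4,
                            year_a = 2008L, year_b = 2021L, seed = 1L) {
  assembly <- match.arg(assembly)
  stopifnot(n_sites >= 1, pool_size >= 3,
            pool_size >= species_lost + 2,
            filtering_strength >= 0, filtering_strength <= 1,
            dominance_shape >= 0, niche_breadth > 0,
            richness_mean >= 2, site_total > 0,
            species_lost >= 0, species_gained >= 0,
            evenness_shift >= 0, breadth_inflation > 0,
            generalist_boost >= 0,
            sequence_length >= 1, kappa > 0)
  structure(list(n_sites = n_sites, pool_size = pool_size,
                 dominance_shape = dominance_shape,
                 niche_breadth = niche_breadth,
                 richness_mean = richness_mean, site_total = site_total,
                 assembly = assembly,
                 filtering_strength = filtering_strength,
                 species_lost = species_lost,
                 species_gained = species_gained,
                 evenness_shift = evenness_shift,
                 breadth_inflation = breadth_inflation,
                 generalist_boost = generalist_boost,
                 sequence_length = sequence_length, kappa = kappa,
                 year_a = as.integer(year_a), year_b = as.integer(year_b),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a Yule (pure-birth) tree
#'
#' A pure-birth tree on `n_leaves` tips, rescaled so the root-to-tip height
#' equals `height` expected substitutions per site (default 0.3, a typical
#' within-family mitochondrial depth). Tips are labeled `sp01`, `sp02`, ...
#'
#' @param n_leaves number of tips, >= 3.
#' @param birth_rate speciation rate of the pure-birth process.
#' @param height target tree height in substitutions/site.
#' @param seed RNG seed (optional).
#' @return an ultrametric `phylo` tree.
#' @export
yule_tree <- function(n_leaves, birth_rate = 1, height = 0.3, seed = NULL) {
  if (n_leaves < 3) stop("tree simulation needs at least 3 leaves")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_leaves, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (height / depth)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_leaves))
  tr
}

#' Evolve aligned sequences along a tree
#'
#' Simulates a Kimura two-parameter substitution process: a root sequence
#' uniform over \{A, C, G, T\} evolves down each branch with transition rate
#' 2 * kappa relative to each transversion rate, so `kappa` is the expected
#' transition:transversion ratio and `kappa = 0.5` reduces to the
#' equal-rates (Jukes-Cantor) process with transitions making up one third
#' of substitutions. Branch lengths are interpreted as expected
#' substitutions per site.
#'
#' @param tree a `phylo` tree with finite branch lengths.
#' @param length_bp alignment length, default 1071 (a full cytochrome b
#'   coding sequence).
#' @param kappa transition:transversion ratio, default 4.
#' @param seed RNG seed (optional).
#' @return a `DNAbin` alignment matrix with rows named by tip label.
#' @export
evolve_sequences <- function(tree, length_bp = 1071, kappa = 4, seed = NULL) {
  if (!inherits(tree, "phylo")) stop("expected a phylo tree")
  if (any(!is.finite(tree$edge.length))) stop("tree branch lengths must be finite")
  if (!is.null(seed)) set.seed(seed)
  # rate order in phangorn: a-c, a-g, a-t, c-g, c-t, g-t
  q <- c(1, 2 * kappa, 1, 1, 2 * kappa, 1)
  sim <- phangorn::simSeq(tree, l = length_bp, Q = q, bf = rep(0.25, 4),
                          type = "DNA")
  as.matrix(ape::as.DNAbin(sim))
}

# draw one survey: site-by-species counts under the configured assembly;
# commonness_weight > 0 tilts site membership toward globally abundant
# species (generalist expansion), the mechanism of biotic homogenization
draw_survey <- function(config, pool, opt, relab, dn, breadth, shape_boost,
                        commonness_weight = 0) {
  n_sites <- config$n_sites
  sites <- sprintf("S%02d", seq_len(n_sites))
  gpos <- if (n_sites == 1) 0.5 else seq(0, 1, length.out = n_sites)
  counts <- matrix(0, n_sites, length(pool), dimnames = list(sites, pool))
  focal <- rep(NA_character_, n_sites)
  s <- config$filtering_strength
  common <- (relab[pool] / max(relab[pool]))^commonness_weight
  for (st in seq_len(n_sites)) {
    m <- exp(-(gpos[st] - opt[pool])^2 / (2 * breadth^2)) * common
    r <- min(length(pool), max(2, stats::rpois(1, config$richness_mean)))
    pick <- switch(config$assembly,
      neutral = sample(pool, r, prob = m),
      filtering = {
        # clade-restricted membership: the r phylogenetically nearest pool
        # members of a focal species (the smallest enclosing clade on an
        # ultrametric tree) are strongly favored; the niche term fades as
        # the filter strengthens
        f <- sample(pool, 1, prob = m)
        focal[st] <- f
        ball <- pool[order(dn[f, pool])][seq_len(r)]
        w <- m^(1 - s) * ifelse(pool %in% ball, 1, exp(-8 * s))
        sample(pool, r, prob = w)
      },
      competition = {
        # sequential assembly with phylogenetic repulsion: candidates close
        # to a resident are penalized by their minimum distance to the
        # residents raised to a strength-scaled power
        chosen <- sample(pool, 1, prob = m)
        while (length(chosen) < r) {
          rest <- setdiff(pool, chosen)
          repulse <- apply(dn[rest, chosen, drop = FALSE], 1, min)^(8 * s)
          w <- m[rest]^(1 - s) * (repulse + 1e-12)
          chosen <- c(chosen, sample(rest, 1, prob = w))
        }
        chosen
      })
    rel <- relab[pick]^(1 + shape_boost)
    rel <- rel / sum(rel)
    counts[st, pick] <- 1 + stats::rpois(length(pick), config$site_total * rel)
  }
  # a survey detects every pool member somewhere: seed undetected species at
  # their best-matching site so realized turnover equals the configured one
  undetected <- pool[colSums(counts) == 0]
  for (sp in undetected) {
    best <- which.max(exp(-(gpos - opt[sp])^2 / (2 * breadth^2)))
    counts[best, sp] <- 1
  }
  list(counts = counts, focal = focal)
}

#' Generate a complete synthetic two-survey bundle
#'
#' Produces everything the analysis pipeline consumes, with known ground
#' truth: a phylogeny over the union species pool, aligned sequences
#' evolved along it, count and biomass matrices for both surveys, and
#' labels recording which species were dropped or added and which focal
#' clades drove filtering. Species are placed on a one-dimensional
#' environmental gradient; per-site assemblages are drawn by
#' niche-match-weighted sampling, modified under the filtering scenario by
#' proximity to a focal clade and under the competition scenario by
#' phylogenetic repulsion from species already present. Abundances follow a
#' lognormal rank-abundance law thinned by Poisson sampling. The later
#' survey removes the lowest-occupancy species, adds the configured number
#' of new pool members, reduces evenness, and widens niches (so among-site
#' dissimilarity declines, emulating biotic homogenization).
#'
#' @param config a [scenario_config()].
#' @param tree optional `phylo` over `pool_size + species_gained` tips; by
#'   default a [yule_tree()] is simulated.
#' @return a `synthetic_bundle` list: `counts_a`, `counts_b`, `biomass_a`,
#'   `biomass_b` ([community_matrix()] objects), `tree`, `sequences`,
#'   `truth` (lost/gained/focal species, traits), `config`.
#' @export
assemble_communities <- function(config = scenario_config(), tree = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n_total <- config$pool_size + config$species_gained
  if (is.null(tree)) {
    tree <- yule_tree(n_total, height = 0.3)
  } else {
    if (length(tree$tip.label) != n_total)
      stop("tree must have pool_size + species_gained = ", n_total, " tips")
  }
  sp <- tree$tip.label
  d <- cophenetic_distances(tree)
  dn <- d / max(d)

  gained <- sample(sp, config$species_gained)
  pool_a <- setdiff(sp, gained)

  opt <- stats::runif(n_total)
  names(opt) <- sp
  relab <- stats::rlnorm(n_total, 0, config$dominance_shape)
  names(relab) <- sp
  mean_weight <- stats::rlnorm(n_total, log(20), 0.8)   # g per individual
  names(mean_weight) <- sp
  mean_length <- stats::rlnorm(n_total, log(8), 0.4)    # cm
  names(mean_length) <- sp

  ya <- draw_survey(config, pool_a, opt, relab, dn, config$niche_breadth, 0,
                    commonness_weight = 0)
  occ_a <- colMeans(ya$counts > 0)
  # rare stream specialists go first: drop the lowest-occupancy species,
  # breaking ties by total abundance
  ord <- order(occ_a, colSums(ya$counts))
  lost <- colnames(ya$counts)[ord][seq_len(config$species_lost)]
  pool_b <- c(setdiff(pool_a, lost), gained)
  yb <- draw_survey(config, pool_b, opt, relab, dn,
                    config$niche_breadth * config$breadth_inflation,
                    config$evenness_shift,
                    commonness_weight = config$generalist_boost)

  biomass <- function(counts) {
    w <- sweep(counts, 2, mean_weight[colnames(counts)], `*`)
    w * stats::rlnorm(length(w), 0, 0.1)
  }
  counts_a <- community_matrix(ya$counts, year = config$year_a)
  counts_b <- community_matrix(yb$counts, year = config$year_b)
  bio_a <- community_matrix(biomass(ya$counts), year = config$year_a,
                            kind = "biomass")
  bio_b <- community_matrix(biomass(yb$counts), year = config$year_b,
                            kind = "biomass")
  seqs <- evolve_sequences(tree, length_bp = config$sequence_length,
                           kappa = config$kappa)

  structure(list(counts_a = counts_a, counts_b = counts_b,
                 biomass_a = bio_a, biomass_b = bio_b,
                 tree = tree, sequences = seqs,
                 truth = list(lost = lost, gained = gained,
                              pool_a = pool_a, pool_b = pool_b,
                              focal_a = ya$focal, focal_b = yb$focal,
                              niche_optimum = opt,
                              rank_abundance = relab,
                              mean_weight = mean_weight,
                              mean_length = mean_length),
                 config = config),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(paste0("synthetic survey bundle (%s assembly, seed %d):\n",
                     "  year %d: %d sites x %d species, N = %d\n",
                     "  year %d: %d sites x %d species, N = %d\n",
                     "  %d species lost, %d gained; tree with %d tips; ",
                     "%d bp alignment\n"),
              x$config$assembly, x$config$seed,
              cm_year(x$counts_a), nrow(x$counts_a), ncol(x$counts_a),
              sum(x$counts_a),
              cm_year(x$counts_b), nrow(x$counts_b), ncol(x$counts_b),
              sum(x$counts_b),
              length(x$truth$lost), length(x$truth$gained),
              length(x$tree$tip.label), ncol(x$sequences)))
  invisible(x)
}

#' Write a synthetic bundle to plain-text files
#'
#' Emits the count and biomass matrices as CSV, the alignment as FASTA, the
#' tree as Newick, and a small manifest of the ground truth.
#'
#' @param bundle a [assemble_communities()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts_a = file.path(dir, "counts_yearA.csv"),
             counts_b = file.path(dir, "counts_yearB.csv"),
             biomass_a = file.path(dir, "biomass_yearA.csv"),
             biomass_b = file.path(dir, "biomass_yearB.csv"),
             tree = file.path(dir, "tree.nwk"),
             sequences = file.path(dir, "alignment.fasta"),
             truth = file.path(dir, "truth.txt"))
  write_community_matrix(bundle$counts_a, paths["counts_a"])
  write_community_matrix(bundle$counts_b, paths["counts_b"])
  write_community_matrix(bundle$biomass_a, paths["biomass_a"])
  write_community_matrix(bundle$biomass_b, paths["biomass_b"])
  ape::write.tree(bundle$tree, paths["tree"])
  ape::write.FASTA(bundle$sequences, paths["sequences"])
  writeLines(c(paste("lost:", paste(bundle$truth$lost, collapse = ",")),
               paste("gained:", paste(bundle$truth$gained, collapse = ",")),
               paste("assembly:", bundle$config$assembly),
               paste("seed:", bundle$config$seed)),
             paths["truth"])
  invisible(paths)
}
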