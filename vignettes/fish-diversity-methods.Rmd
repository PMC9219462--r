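---
title: "Methods: multi-faceted diversity analysis for repeated stream-fish surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-faceted diversity analysis for repeated stream-fish surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverdiv)
```

riverdiv compares riverine fish communities between two surveys of the same
site network across three facets: species diversity, compositional
structure, and phylogenetic structure. This vignette is the package's
account of the statistical machinery, its assumptions, and the design
decisions behind it.

## Data model

Everything consumes a `community_matrix`: sites in rows, species in
columns, with a survey-year label and a `kind` of either `count`
(individuals, integer) or `biomass` (grams, real). Count and biomass data
are deliberately separate objects — the only statistic that uses both is
the IRI. A species counts as present in a survey only when its total
abundance is positive; species retained in metadata but never observed are
treated as absent, so `compare_species_lists()` reports observation-based
turnover.

## Species diversity

Per community the package reports richness $S$, abundance $N$, and, with
$p_i = N_i / \sum_j N_j$:

- Shannon–Wiener $H = -\sum p_i \ln p_i$ (natural log throughout; indices
  are kept at full precision and rounded only for display),
- Margalef $D = (S-1)/\ln N$,
- Gini–Simpson $F = 1 - \sum p_i^2$ (field reports often label this a
  "dominance" index; larger values in fact mean *less* dominance — the
  package implements the printed diversity form and leaves interpretation
  to the analyst),
- Pielou $J = H / \ln S$, undefined ($NA$ with a warning) for $S < 2$.

Pooled (reserve-level) indices are computed on counts summed across sites
rather than averaged per site, matching the convention of reporting a
single $N$ per survey. Dominance uses the index of relative importance,
$IRI_i = (\%N_i + \%W_i) \times f_i$ with percentages on the 0–100 scale
and occurrence frequency $f_i$ on 0–1, so $IRI \le 200$. No published
cutoff exists on this scaling; the default flag of $IRI \ge 10$ is a
configurable convenience, not a standard.

Sampling completeness uses the classical Chao1 estimator
$\hat S = S_{obs} + f_1^2 / (2 f_2)$ with the bias-corrected fallback
$S_{obs} + f_1(f_1 - 1)/2$ when doubletons are absent, and completeness
$= S_{obs} / \hat S$. The rarefaction curve is the exact hypergeometric
expectation $E[S_m] = \sum_i (1 - \binom{N - N_i}{m} / \binom{N}{m})$,
computed via `vegan::rarefy()`. Extrapolation beyond $N$ and
coverage-based confidence intervals are out of scope.

## Beta diversity and homogenization

Incidence-based dissimilarity is partitioned into spatial turnover and
nestedness. For a site pair with $a$ shared and $b, c$ exclusive species:

$$\beta_{sor} = \frac{b + c}{2a + b + c}, \qquad
  \beta_{sim} = \frac{\min(b, c)}{a + \min(b, c)}, \qquad
  \beta_{sne} = \beta_{sor} - \beta_{sim},$$

with the additive identity holding exactly by construction. Two summary
modes are provided: the arithmetic mean over all site pairs
(`beta_mean_pairwise()`, the default, since survey-level totals are
usually described as pairwise) and Baselga's multiple-site construction
(`beta_multisite()`) built from $\sum \min(b_{ij}, b_{ji})$,
$\sum \max(b_{ij}, b_{ji})$ and $A = \sum S_i - S_T$. No in-environment
package implements this partition, so it is authored here and checked
against hand-computed cases and fuzz invariants.

The temporal contrast `homogenization()` returns the *exact* difference
$\Delta\beta_{sor} = \beta_{sor}(A) - \beta_{sor}(B)$ of whatever
partitions it is given; positive values (earlier survey more dissimilar)
indicate biotic homogenization. Published deltas computed from rounded
annual values can disagree with the rounded delta of unrounded values by
one unit in the last digit; the package never rounds inside the pipeline.

## Assemblage structure

Counts are fourth-root transformed before resemblance analysis. The
transform is the *root* $x^{1/4}$: severe down-weighting of abundant
species is the entire point of the step, and the root (not the fourth
power, which would amplify extremes) is what the standard
PRIMER-style workflow applies. Bray–Curtis dissimilarity
$d = \sum |x_i - y_i| / \sum (x_i + y_i)$ then feeds:

- UPGMA (group-average) clustering, exported as Newick when needed;
- NMDS minimizing Kruskal stress-1 with weak (primary) monotone
  regression, 50 random restarts by default, best configuration returned
  centered at the origin (`vegan::metaMDS` is the engine; rank-based, so
  any monotone transform of the input leaves the solution unchanged);
- ANOSIM, $R = (\bar r_B - \bar r_W) / (M/2)$ on the ranks of all
  pairwise dissimilarities, tested one-sided by label permutation with
  the $(c + 1)/(n_{perm} + 1)$ estimator (999 permutations by default).
  ANOSIM's statistic is $R$, not $R^2$; survey reports occasionally print
  it squared, and the package reports plain $R \in [-1, 1]$;
- SIMPER on the same transformed matrix used for Bray–Curtis (not raw
  counts), decomposing the average between-group dissimilarity into
  per-species contributions that sum to it exactly.

Group labels for ANOSIM/SIMPER are an input: in `run_full_analysis()` they
default to cutting the UPGMA dendrogram into three groups (the typical
figure-style presentation) but can and should be supplied externally when
clustering and testing must stay independent.

## Phylogenetic structure

From an aligned FASTA (the marker emulated throughout is a 1071-bp
mitochondrial cytochrome *b* alignment) the package computes pairwise
distances with pairwise deletion of gap/ambiguous sites — Kimura
two-parameter by default (the conventional default for mitochondrial
barcodes; the substitution model behind published trees is often
unstated), uncorrected *p*-distance by option — then a Saitou–Nei
neighbor-joining tree (`ape::nj`, negative branch estimates clamped to
zero with a warning). A precomputed tree can be supplied instead.

Community phylogenetic structure is measured per site as the unweighted
mean pairwise cophenetic distance (MPD) of the species present. The null
model draws, 999 times by default, the same number of species uniformly
without replacement from the species pool and recomputes MPD — identical
in distribution to shuffling taxa labels on the tree. The net relatedness
index is

$$NRI = \frac{\overline{MPD_{null}} - MPD_{obs}}{SD(MPD_{null})},$$

i.e. $-1 \times$ the standardized effect size of MPD: positive when
co-occurring species are closer on the tree than expected (phylogenetic
clustering, conventionally read as environmental filtering), negative
under overdispersion (read as competition). Published tables in this
domain sometimes display the formula with the opposite sign while
printing values consistent with the convention above; the package follows
the convention that reproduces such tables, and `assembly_call()` is a
pure function of the sign. The null SD uses the population
(divide-by-$n$) form; at 999 draws the difference from the sample form is
below 0.1%. Communities with fewer than two species have undefined MPD
and yield an `NA` row; a community equal to its pool has a degenerate
(zero-SD) null and yields `NA` too.

Per-site NRI is computed against the survey's own species pool. A
survey-total community equals its own pool, which would be degenerate, so
`run_full_analysis()` scores the total row against the union pool of both
surveys — the one place a cross-survey pool is used.

## The synthetic generator

`assemble_communities()` produces a fully labeled two-survey bundle so
that every stage of the pipeline can be tested end to end without any
field data. Its defaults describe a small montane stream network: 13
sites, a 17-species pool, about 100 individuals and 7 species per site,
strong dominance (lognormal rank abundance with $\sigma = 1.8$, giving a
handful of clearly dominant species), 5 species lost and 4 gained between
surveys, and a later survey with reduced evenness and more similar sites.

Mechanics, in order:

1. A Yule tree over the union pool (height 0.3 substitutions/site, a
   typical within-family mitochondrial depth) and sequences evolved along
   it under a K2P process with transition:transversion ratio 4
   (`kappa = 0.5` is the equal-rates special case).
2. Species receive iid uniform niche optima on a 0–1 gradient; sites sit
   on an even grid of that gradient. Per-site membership is drawn without
   replacement with weights proportional to Gaussian niche match
   (breadth 0.25).
3. Assembly mechanisms modify the weights. *Filtering* picks a focal
   species and strongly favors its `r` phylogenetically nearest pool
   members — the smallest enclosing clade on an ultrametric tree — with
   the niche term fading as strength grows; this clade-restricted design
   was chosen after a pure exponential-distance kernel produced too many
   borderline communities when the focal species had no close relatives.
   *Competition* assembles sequentially, penalizing candidates by their
   minimum distance to residents raised to a strength-scaled power. At
   `filtering_strength = 0` both reduce exactly to the neutral draw.
   Because niche optima are independent of the phylogeny, neutral
   assemblages are phylogenetically random and NRI is centered at zero.
4. Abundances are Poisson draws around lognormal rank-abundance shares;
   every pool member is seeded into its best-matching site if otherwise
   undetected, so the realized species lists equal the configured pools
   and temporal turnover is exact by construction.
5. The later survey drops the lowest-occupancy species (rare specialists
   go first), adds the configured newcomers, raises abundance shares to
   the power $1 + 0.5$ (evenness decline), widens niches by 1.35 and
   tilts membership toward globally abundant species
   (`generalist_boost = 0.5`). The last two emulate generalist expansion,
   the mechanism behind biotic homogenization, and were set so that the
   qualitative two-survey pattern — pooled $H$ declines, mean-pairwise
   $\beta_{sor}$ declines, turnover exceeds nestedness in both surveys —
   appears in well over 80% of seeds while keeping the decline gentle
   rather than collapsing the site structure.
6. Biomass is counts times a per-species lognormal mean weight (median
   20 g, so most species fall under 50 g) with 10% individual noise;
   body lengths are lognormal around 8 cm.

What the generator does *not* emulate: real river-network topology
(sites are a 1-D gradient), gear-specific detection bias, seasonal
structure, and any attempt to match published per-river tables
numerically — scenarios match structure, not numbers. Passing tests
therefore demonstrate that the estimators recover known mechanisms and
satisfy their identities, not that any particular published value is
reproduced beyond the closed-form identities checked directly.

## Numerical and reproducibility choices

- Natural logs everywhere; no rounding inside the pipeline (display
  rounding only: indices to 2 decimals, MPD/SD/NRI to 3).
- `run_full_analysis()` draws one sub-seed per stochastic stage (NMDS,
  ANOSIM, null models per survey) from its master seed, so reports are
  bit-reproducible and the manifest records everything needed to rerun.
- Problem sizes used by the test suite and the acceptance script — e.g.
  200 communities per assembly scenario at 999 null draws, 500 null
  datasets for the ANOSIM error-rate check, 25 seeds for the temporal
  pattern — were chosen to make Monte-Carlo error small relative to the
  margins being tested while keeping a full run in the order of a minute
  or two.
- Ties in `min(b, c)` need no tie-break (the formulas are symmetric);
  UPGMA inherits `hclust` tie behavior; NMDS local optima are handled by
  restarts, and two independent restart sets agreeing within $10^{-3}$
  stress is part of the test suite.

## Known limitations

- No abundance-weighted MPD, no nearest-taxon statistics, no bootstrap
  support on trees, no substitution-model selection.
- No Hill-number framework or extrapolated richness.
- ANOSIM and SIMPER inherit the usual caveats (sensitivity to
  within-group dispersion differences); the package reports, it does not
  adjudicate.
- The homogenization direction is a point contrast of two surveys; with
  one value per survey there is no sampling distribution unless the user
  bootstraps externally.
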