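# riverdiv

Multi-faceted diversity analysis for repeated stream-fish surveys.

Small river networks are resurveyed years apart to ask three questions:
has diversity declined, have the communities of different rivers become
more alike (biotic homogenization), and what assembly mechanism —
environmental filtering or competition — structures the communities?
riverdiv implements the full analysis pipeline a fish ecologist runs to
answer them from site-by-species matrices, specimen records, and a
phylogeny (or an aligned cytochrome *b* matrix to build one from):

- **Species diversity** — Shannon–Wiener `H = −Σ pᵢ ln pᵢ`, Margalef
  `D = (S−1)/ln N`, Gini–Simpson `F = 1 − Σ pᵢ²`, Pielou `J = H/ln S`,
  per site and pooled; dominance by the index of relative importance
  `IRI = (%N + %W) × f`; Chao1 sampling completeness and exact
  abundance-based rarefaction.
- **Beta diversity** — Sørensen dissimilarity partitioned into spatial
  turnover and nestedness, `β_sor = β_sim + β_sne`, as a mean over site
  pairs or as Baselga's multiple-site version, plus the temporal contrast
  `Δβ_sor` whose sign diagnoses homogenization.
- **Assemblage structure** — fourth-root transform, Bray–Curtis
  dissimilarity, UPGMA clustering, NMDS (Kruskal stress-1), ANOSIM with
  permutation tests, and SIMPER species contributions.
- **Phylogenetic structure** — K2P/p-distances with pairwise deletion,
  neighbor-joining trees, mean pairwise distance (MPD), richness-preserving
  null models, and the net relatedness index
  `NRI = (mean(MPD_null) − MPD_obs) / SD(MPD_null)`, with NRI > 0 read as
  filtering and NRI < 0 as competition.
- **Synthetic surveys** — a generator producing two-survey bundles
  (counts, biomass, tree, sequences) with known ground truth under
  neutral, filtering, or competition assembly, for testing and power
  analysis.

## Worked example

```r
library(riverdiv)

b <- assemble_communities(scenario_config(seed = 1))
b
#> synthetic survey bundle (neutral assembly, seed 1):
#>   year 2008: 13 sites x 17 species, N = 1380
#>   year 2021: 13 sites x 16 species, N = 1449
#>   5 species lost, 4 gained; tree with 21 tips; 1071 bp alignment

report <- run_full_analysis(b, seed = 1)
report
#> diversity report (seed 1): surveys 2008 vs 2021
#>   richness 17 -> 16 (5 lost, 4 gained)
#>   pooled H 2.32 -> 1.26, J 0.82 -> 0.46
#>   mean-pairwise beta_sor 0.71 -> 0.44 (delta 0.27, homogenization)
#>   ANOSIM R: 0.61 (A), 0.82 (B)
#>   total NRI: 0.59 (A), -1.18 (B)
```

The report reads as a survey comparison: diversity fell (pooled Shannon
2.32 → 1.26 and evenness 0.82 → 0.46, driven by the generator's evenness
decline), the rivers' communities converged (mean pairwise Sørensen
dissimilarity 0.71 → 0.44, a positive `Δβ_sor`, i.e. homogenization), the
rivers still differ significantly in composition (ANOSIM R = 0.61 and
0.82), and the reserve-wide species set shows no strong phylogenetic
structure in either year under this neutral-assembly simulation.

Each piece is available on its own:

```r
alpha_table(b$counts_a, pooled = TRUE)
#>         S    N     H     D     F    J
#> pooled 17 1380 2.324 2.213 0.873 0.82

head(report$nri$a, 4)   # per-river null-model summary
#>   site richness mpd_null_mean mpd_obs sd_null    nri    assembly
#> 1  S01       11         0.486   0.493   0.021 -0.322 competition
#> 2  S02        4         0.484   0.494   0.064 -0.151 competition
#> 3  S03        2         0.487   0.539   0.140 -0.370 competition
#> 4  S04        4         0.488   0.530   0.067 -0.627 competition

head(report$iri$a, 3)   # dominant species by IRI
#>   species pct_n pct_w    f  iri dominant
#> 1    sp12  21.1  15.2 0.38 13.9     TRUE
#> 2    sp10  14.3  18.3 0.38 12.5     TRUE
#> 3    sp03  18.7  19.1 0.31 11.6     TRUE
```

Closed-form index checks against published survey summaries are direct
function calls:

```r
margalef_index(17, 1320)        # 2.23 from S = 17 species, N = 1320
pielou_evenness(1.72, 17)       # 0.61 from H = 1.72, S = 17
nri(0.149, 0.159, 0.017)        # 0.588: clustered community, NRI > 0
```

See `vignette("fish-diversity-methods")` for the statistical details,
generator design, and limitations.

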