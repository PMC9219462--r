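Package: riverdiv
Title: Multi-Faceted Diversity Analysis for Temporal Stream-Fish Surveys
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing riverine fish communities between repeated
    surveys: alpha diversity (Shannon, Margalef, Gini-Simpson, Pielou),
    dominance via the index of relative importance (IRI), Chao1 sampling
    completeness and abundance-based rarefaction, incidence-based beta
    diversity partitioned into spatial turnover and nestedness with a
    temporal homogenization contrast, assemblage structure via fourth-root
    transformed Bray-Curtis dissimilarity with UPGMA clustering, NMDS
    ordination, ANOSIM and SIMPER, and phylogenetic community structure from
    aligned cytochrome b sequences or a supplied tree (neighbor-joining,
    mean pairwise distance, richness-preserving null models, net relatedness
    index). A synthetic-data generator produces survey bundles with known
    assembly mechanisms for end-to-end testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
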