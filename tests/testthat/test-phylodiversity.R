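test_that("FASTA reading validates alignment structure", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp1", "ACGTACGTACGT", ">sp2", "acgtacgtacgn", ">sp3",
               "ACGTACGTACGA"), path)
  seqs <- read_fasta(path)
  expect_equal(dim(seqs), c(3L, 12L))
  chars <- as.character(seqs)
  expect_identical(unname(chars["sp2", 12]), "n")   # ambiguity retained
  expect_identical(unname(chars["sp2", 1]), "a")    # case normalized internally

  writeLines(c(">sp1", "ACGTACGTAC", ">sp2", "ACGTACGTACGT"), path)
  expect_error(read_fasta(path), "unequal alignment length")
  writeLines(c(">sp1", "ACGT", ">sp1", "ACGT"), path)
  expect_error(read_fasta(path), "duplicate sequence id")
})

test_that("p-distance handles mismatches and pairwise gap exclusion", {
  seqs <- dnabin_from_strings(c("ACGT", "GCGT", "ACG-"), c("a", "b", "c"))
  d <- as.matrix(p_distance(seqs))
  expect_equal(d["a", "b"], 0.25)   # one of four sites differs
  expect_equal(d["a", "c"], 0)      # gap site excluded pairwise
  expect_equal(d["a", "a"], 0)

  # zero comparable sites is an error
  bad <- dnabin_from_strings(c("AC--", "--GT"), c("a", "b"))
  expect_error(p_distance(bad), "non-comparable")
})

test_that("K2P distance matches its closed form", {
  # P = 0.25, Q = 0: d = (1/2) ln 2
  seqs <- dnabin_from_strings(c("ACGT", "GCGT"), c("a", "b"))
  expect_equal(as.numeric(k2p_distance(seqs)), 0.5 * log(2), tolerance = 1e-12)
  # P = 0, Q = 0.25 (A->C transversion):
  # d = (1/2) ln(1/(1 - Q)) + (1/4) ln(1/(1 - 2Q))
  seqs2 <- dnabin_from_strings(c("ACGT", "CCGT"), c("a", "b"))
  want <- 0.5 * log(1 / (1 - 0.25)) + 0.25 * log(1 / (1 - 0.5))
  expect_equal(as.numeric(k2p_distance(seqs2)), want, tolerance = 1e-12)
  # identical sequences at distance zero
  same <- dnabin_from_strings(c("ACGT", "ACGT"), c("a", "b"))
  expect_equal(as.numeric(k2p_distance(same)), 0)
  # saturation (1 - 2P - Q <= 0) is an error
  sat <- dnabin_from_strings(c("AAAAGGGG", "GGGGAAAA"), c("a", "b"))
  expect_error(k2p_distance(sat), "saturated")
})

test_that("neighbor joining is exact on additive matrices", {
  # 3 taxa: closed-form branch lengths
  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_tree(d3)
  bl <- setNames(tr3$edge.length[tr3$edge[, 2] <= 3],
                 tr3$tip.label[tr3$edge[tr3$edge[, 2] <= 3, 2]])
  expect_equal(bl[["A"]], (3 + 5 - 6) / 2)
  expect_equal(bl[["B"]], (3 + 6 - 5) / 2)
  expect_equal(bl[["C"]], (5 + 6 - 3) / 2)

  # 4-taxon additive matrix: topology AB|CD and branch lengths recovered
  d4 <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr4 <- nj_tree(d4)
  expect_equal(stats::cophenetic(tr4)[LETTERS[1:4], LETTERS[1:4]], d4,
               tolerance = 1e-12)
  expect_error(nj_tree(d4[1:2, 1:2]), "at least 3")

  # tree -> cophenetic -> NJ round trip on random additive matrices
  set.seed(51)
  for (i in 1:20) {
    ref <- random_additive_matrix(8)
    back <- stats::cophenetic(nj_tree(ref$d))
    expect_equal(back[rownames(ref$d), colnames(ref$d)], ref$d,
                 tolerance = 1e-9)
  }
})

test_that("cophenetic distances equal hand-computed path lengths", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  d <- cophenetic_distances(tr)
  expect_equal(d["A", "B"], 3)
  expect_equal(d["A", "C"], 5)
  expect_equal(d["B", "D"], 7)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  two <- ape::read.tree(text = "(A:1,B:2);")
  expect_equal(cophenetic_distances(two)["A", "B"], 3)
})

test_that("observed MPD is the mean over present pairs", {
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(mpd_observed(c("a", "b", "c"), d), 4)
  expect_equal(mpd_observed(c("a", "b"), d), 2)
  # named incidence vector form
  expect_equal(mpd_observed(c(a = 3, b = 0, c = 1), d), 4)
  expect_warning(m1 <- mpd_observed("a", d), "fewer than 2")
  expect_true(is.na(m1))
  expect_error(mpd_observed(c("a", "zz"), d), "missing from the distance")
})

test_that("the null MPD distribution matches exhaustive enumeration", {
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nd <- null_mpd(2, d, n_rand = 3000, seed = 7)
  # support is exactly the three pairwise distances
  expect_setequal(unique(nd$values), c(2, 4, 6))
  # mean tends to their average
  expect_equal(nd$mean, mean(c(2, 4, 6)), tolerance = 0.1)
  # population-SD convention
  expect_equal(nd$sd, sqrt(mean((nd$values - nd$mean)^2)), tolerance = 1e-12)

  # determinism: same seed, same distribution
  nd2 <- null_mpd(2, d, n_rand = 50, seed = 123)
  nd3 <- null_mpd(2, d, n_rand = 50, seed = 123)
  expect_identical(nd2$values, nd3$values)

  expect_error(null_mpd(4, d), "exceeds the species pool")
  expect_error(null_mpd(1, d), "at least 2")
})

test_that("NRI arithmetic, sign convention, and assembly calls", {
  # clustered community: observed below the null mean gives positive NRI
  expect_equal(nri(0.149, 0.159, 0.017), (0.159 - 0.149) / 0.017)
  expect_gt(nri(0.149, 0.159, 0.017), 0)
  expect_equal(nri(0.5, 0.5, 0.1), 0)
  expect_warning(z <- nri(0.5, 0.5, 0), "undefined")
  expect_true(is.na(z))
  expect_identical(assembly_call(c(1.2, -0.4, 0, NA)),
                   c("environmental_filtering", "competition",
                     "indeterminate", "indeterminate"))
})

test_that("observed MPD agrees with an independent implementation", {
  skip_if_not_installed("picante")
  b <- shared_bundle()
  d <- cophenetic_distances(b$tree)
  x <- unclass(b$counts_a)[, ]
  mine <- sapply(seq_len(nrow(x)), function(i) {
    suppressWarnings(mpd_observed(colnames(x)[x[i, ] > 0], d))
  })
  ref <- picante::mpd(x, d[colnames(x), colnames(x)])
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("NRI agrees with an independent null-model implementation", {
  skip_if_not_installed("picante")
  set.seed(52)
  tr <- yule_tree(15)
  d <- cophenetic_distances(tr)
  x <- matrix(0, 4, 15, dimnames = list(paste0("s", 1:4), tr$tip.label))
  for (i in 1:4) x[i, sample(15, 6)] <- 1
  mine <- nri_table(community_matrix(x), tr, n_rand = 999, seed = 9,
                    pool = tr$tip.label)
  ref <- picante::ses.mpd(x, d, null.model = "taxa.labels", runs = 999)
  # NRI is minus the standardized effect size; agreement up to null noise
  expect_equal(mine$nri, -ref$mpd.obs.z, tolerance = 0.35)
  expect_equal(mine$mpd_obs, ref$mpd.obs, tolerance = 1e-10)
})

test_that("NRI tables handle sub-2-species sites and degenerate pools", {
  set.seed(53)
  tr <- yule_tree(6)
  x <- matrix(0, 3, 6, dimnames = list(paste0("s", 1:3), tr$tip.label))
  x[1, 1] <- 1                    # single-species site -> NA row
  x[2, ] <- 1                     # full-pool site -> degenerate null
  x[3, c(1, 3, 5)] <- 1
  tab <- nri_table(community_matrix(x), tr, n_rand = 199, seed = 11,
                   pool = tr$tip.label)
  expect_true(is.na(tab$nri[1]))
  expect_identical(tab$assembly[1], "indeterminate")
  expect_true(is.na(tab$nri[2]))
  expect_equal(tab$sd_null[2], 0)
  expect_false(is.na(tab$nri[3]))
  expect_identical(tab$assembly[3], assembly_call(tab$nri[3]))
  # reproducible as a whole from the master seed
  tab2 <- nri_table(community_matrix(x), tr, n_rand = 199, seed = 11,
                    pool = tr$tip.label)
  expect_identical(tab$nri, tab2$nri)
  expect_error(nri_table(community_matrix(x[, 1:5]), tr, pool = c("sp01", "zz")),
               "missing from the tree")
})
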