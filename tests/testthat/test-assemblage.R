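test_that("fourth-root transform is the monotone root, not the power", {
  m <- matrix(c(16, 0, 1, 81), 2, 2,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  t4 <- fourth_root_transform(community_matrix(m))
  expect_equal(t4["s1", "a"], 2)
  expect_equal(t4["s1", "b"], 1)
  expect_equal(t4["s2", "a"], 0)
  expect_equal(t4["s2", "b"], 3)
  x <- sort(runif(20, 0, 100))
  expect_true(all(diff(fourth_root_transform(matrix(x, 1, 20,
    dimnames = list("s", paste0("sp", 1:20))))[1, ]) > 0))
  expect_error(fourth_root_transform(matrix(-1, 1, 1,
    dimnames = list("s", "sp"))), "non-negative")
})

test_that("Bray-Curtis matches hand arithmetic and conventions", {
  m <- rbind(x = c(1, 2, 3), y = c(2, 2, 1))
  colnames(m) <- paste0("sp", 1:3)
  d <- bray_curtis(m)
  expect_equal(as.numeric(d), 3 / 11)

  same <- rbind(a = c(1, 2), b = c(1, 2))
  colnames(same) <- c("s1", "s2")
  expect_equal(as.numeric(bray_curtis(same)), 0)
  disjoint <- rbind(a = c(5, 0), b = c(0, 3))
  colnames(disjoint) <- c("s1", "s2")
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)

  empty_pair <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  colnames(empty_pair) <- c("s1", "s2")
  expect_warning(d2 <- bray_curtis(empty_pair), "empty")
  expect_equal(as.matrix(d2)["a", "b"], 0)
})

test_that("Bray-Curtis after fourth root is only jointly scale-invariant", {
  set.seed(41)
  m <- matrix(rpois(20, 10) + 1, 4, 5,
              dimnames = list(paste0("s", 1:4), paste0("sp", 1:5)))
  d1 <- bray_curtis(fourth_root_transform(m))
  d2 <- bray_curtis(fourth_root_transform(m * 16))
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-12)
  # scaling a single site changes the distances
  m3 <- m
  m3[1, ] <- m3[1, ] * 16
  d3 <- bray_curtis(fourth_root_transform(m3))
  expect_false(isTRUE(all.equal(as.numeric(d1), as.numeric(d3))))
})

test_that("UPGMA reproduces group-average merge heights", {
  d <- matrix(c(0, 0.2, 0.8,
                0.2, 0, 0.8,
                0.8, 0.8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- upgma_cluster(d)
  expect_equal(sort(hc$height), c(0.2, 0.8))
  expect_true(all(diff(hc$height) >= 0))

  # ultrametric input is reproduced exactly
  set.seed(46)
  tr <- ape::rcoal(5)
  du <- stats::cophenetic(tr)
  hc2 <- upgma_cluster(du)
  back <- stats::cophenetic(ape::as.phylo(hc2))
  expect_equal(back[rownames(du), colnames(du)], du, tolerance = 1e-9)

  two <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(upgma_cluster(two)$height, 0.4)
  expect_match(dendrogram_newick(hc), "^\\(.*\\);$")
})

test_that("NMDS recovers exactly embeddable configurations with near-zero stress", {
  set.seed(42)
  pts <- matrix(rnorm(10, sd = 2), 5, 2)
  d <- dist(pts)
  fit <- nmds_ordination(d, k = 2, n_restarts = 20, seed = 1)
  expect_lt(fit$stress, 0.01)
  expect_equal(colMeans(fit$points), c(0, 0), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(nmds_ordination(dist(c(1, 2, NA))), "non-finite")
})

test_that("NMDS stress is rank-invariant and monotone in dimensionality", {
  set.seed(43)
  m <- matrix(rpois(28, 8), 4, 7,
              dimnames = list(paste0("s", 1:4), paste0("sp", 1:7)))
  d <- bray_curtis(m)
  s1 <- nmds_ordination(d, k = 2, n_restarts = 30, seed = 2)$stress
  # a monotone transform of the dissimilarities preserves ranks, so stress
  dsq <- d^2
  s2 <- nmds_ordination(dsq, k = 2, n_restarts = 30, seed = 3)$stress
  expect_equal(s1, s2, tolerance = 0.01)
  # restart robustness: independent seeds reach the same optimum
  s3 <- nmds_ordination(d, k = 2, n_restarts = 30, seed = 99)$stress
  expect_equal(s1, s3, tolerance = 1e-3)
  # with k = n - 1 any small matrix embeds at least as well as k = 2
  sk <- nmds_ordination(d, k = 3, n_restarts = 30, seed = 4)$stress
  expect_lte(sk, s1 + 1e-6)
})

test_that("ANOSIM matches its rank-formula oracle and permutation null", {
  set.seed(44)
  # maximal separation: every between-group distance above every within
  g <- rep(c("u", "v"), each = 5)
  m <- rbind(matrix(rnorm(10, 0, 0.01), 5), matrix(rnorm(10, 10, 0.01), 5))
  d <- dist(m)
  res <- anosim_test(d, g, n_permutations = 199, seed = 1)
  expect_equal(res$R, 1)
  expect_lte(res$p_value, 0.05)
  expect_equal(res$R, oracle_anosim_R(d, g))

  # permutation p agrees with the exhaustive enumeration on n = 6; the
  # grouping-preserving relabelings tie the observed statistic exactly, so
  # the estimator is bracketed by the strict and tie-inclusive counts
  m2 <- matrix(rnorm(12), 6, 2)
  d2 <- dist(m2)
  g2 <- rep(c("u", "v"), each = 3)
  res2 <- anosim_test(d2, g2, n_permutations = 999, seed = 2)
  expect_equal(res2$R, oracle_anosim_R(d2, g2), tolerance = 1e-12)
  p_ex <- oracle_anosim_p_exhaustive(d2, g2)
  expect_gte(res2$p_value, p_ex$strict - 0.06)
  expect_lte(res2$p_value, p_ex$tied + 0.06)

  expect_error(anosim_test(d, rep("u", 10)), "2 groups")
  expect_error(anosim_test(d, g, n_permutations = 10), "99")
})

test_that("SIMPER matches brute-force enumeration and its sum identity", {
  set.seed(45)
  m <- matrix(rpois(24, 6), 4, 6,
              dimnames = list(paste0("s", 1:4), paste0("sp", 1:6)))
  g <- c("p", "p", "q", "q")
  tab <- simper_table(m, g, pair = c("p", "q"), percent = FALSE)
  want <- oracle_simper(m, g, c("p", "q"))
  expect_equal(setNames(tab$average_dissimilarity, tab$species),
               want[tab$species], tolerance = 1e-12)
  # contributions sum to the average between-group Bray-Curtis
  bt <- as.matrix(bray_curtis(m))[1:2, 3:4]
  expect_equal(attr(tab, "average_dissimilarity"), mean(bt), tolerance = 1e-12)
  expect_equal(sum(tab$contribution_pct), 100)
  expect_true(all(diff(tab$average_dissimilarity) <= 1e-15))

  # single shared species contributes everything
  m1 <- matrix(c(3, 1, 8, 5), 4, 1, dimnames = list(paste0("s", 1:4), "only"))
  t1 <- simper_table(m1, g, pair = c("p", "q"))
  expect_equal(t1$contribution_pct, 100)

  expect_error(simper_table(m, g, pair = c("p", "p")), "distinct")
})
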