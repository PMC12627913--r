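test_that("pseudo_f matches the double-loop oracle and hand decomposition", {
  # 4-point hand matrix, groups {1,2} / {3,4}
  d <- matrix(0, 4, 4)
  d[upper.tri(d)] <- c(0.2, 0.8, 0.9, 0.7, 0.6, 0.3)
  d <- d + t(d)
  labels <- c("g1", "g1", "g2", "g2")
  ss_tot <- sum(d[upper.tri(d)]^2) / 4
  ss_w <- (0.2^2) / 2 + (0.3^2) / 2
  f_hand <- ((ss_tot - ss_w) / 1) / (ss_w / 2)
  res <- pseudo_f(d, labels)
  expect_equal(res$f_stat, f_hand, tolerance = 1e-12)
  expect_equal(res$r2, (ss_tot - ss_w) / ss_tot, tolerance = 1e-12)
  expect_equal(res$df_among, 1L)
  expect_equal(res$df_within, 2L)
  # oracle equivalence on random instances, N <= 12, 2-3 groups
  set.seed(43)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    X <- matrix(rnorm(2 * n), n, 2)
    D <- as.matrix(dist(X))
    labels <- sample(letters[1:sample(2:3, 1)], n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    o <- oracle_pseudo_f(D, labels)
    r <- pseudo_f(D, labels)
    expect_equal(r$f_stat, o$f, tolerance = 1e-10)
    expect_equal(r$r2, o$r2, tolerance = 1e-10)
    # relabeling invariance: permute points and labels together
    perm <- sample(n)
    r2 <- pseudo_f(D[perm, perm], labels[perm])
    expect_equal(r2$f_stat, r$f_stat, tolerance = 1e-10)
  }
  # perfect separation: duplicated points within groups -> infinite F
  Xs <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  rs <- pseudo_f(as.matrix(dist(Xs)), c("a", "a", "b", "b"))
  expect_identical(rs$f_stat, Inf)
  expect_error(pseudo_f(d, rep("a", 4)), "2 groups")
})

test_that("pseudo_f agrees with vegan::adonis2", {
  skip_if_not_installed("vegan")
  ds <- random_dataset(25, 10, seed = 47)
  D <- dissimilarity_matrix(ds)
  labels <- rep(c("x", "y"), 5)
  r <- pseudo_f(D, labels)
  fit <- vegan::adonis2(as.dist(D$d) ~ grp,
                        data = data.frame(grp = labels), permutations = 2)
  expect_equal(r$f_stat, fit$F[1], tolerance = 1e-10)
  expect_equal(r$r2, fit$R2[1], tolerance = 1e-10)
})

test_that("exhaustive permanova enumerates all distinct assignments", {
  # N = 4 balanced: 6 label vectors in 3 relabeling-equivalent pairs,
  # so p must be one of 1/3, 2/3, 1
  set.seed(53)
  for (i in 1:10) {
    X <- matrix(rnorm(8), 4, 2)
    D <- as.matrix(dist(X))
    res <- permanova(D, c("a", "a", "b", "b"))
    expect_true(res$exhaustive)
    expect_equal(res$n_perm, 6)
    expect_true(any(abs(res$p_value - c(1 / 3, 2 / 3, 1)) < 1e-12))
  }
  # exhaustive and sampled p agree within 3 Monte-Carlo SE (N = 8 balanced)
  set.seed(59)
  X <- matrix(rnorm(16), 8, 2)
  D <- as.matrix(dist(X))
  labels <- rep(c("a", "b"), each = 4)
  p_ex <- permanova(D, labels, exhaustive = TRUE)$p_value
  p_s <- permanova(D, labels, n_perm = 9999, seed = 3,
                   exhaustive = FALSE)$p_value
  se <- sqrt(p_ex * (1 - p_ex) / 9999)
  expect_lt(abs(p_ex - p_s), 3 * se + 1e-4)
})

test_that("sampled permanova is seeded and never returns p = 0", {
  ds <- random_dataset(30, 9, seed = 61)
  D <- dissimilarity_matrix(ds)
  labels <- rep(c("a", "b", "c"), 3)
  r1 <- permanova(D, labels, n_perm = 99, seed = 5, exhaustive = FALSE)
  r2 <- permanova(D, labels, n_perm = 99, seed = 5, exhaustive = FALSE)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 100)
  expect_false(r1$exhaustive)
  expect_error(permanova(D, labels, n_perm = 0), "n_perm")
})

test_that("hierarchical clustering reproduces hand agglomerations", {
  # d(A,B)=1, d(A,C)=4, d(B,C)=5
  d <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  for (linkage in c("complete", "single", "average")) {
    tr <- hierarchical_cluster(d, linkage)
    expect_equal(tr$merges[1, ], c(-1L, -2L))   # (A,B) first at height 1
    expect_equal(tr$heights[1], 1)
    expect_equal(tr$heights[2],
                 switch(linkage, complete = 5, single = 4, average = 4.5))
  }
  # two points at distance d: single merge at height d
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- hierarchical_cluster(d2)
  expect_equal(t2$heights, 0.4)
  expect_error(hierarchical_cluster(d2, "ward"), "arg")
  # ultrametric input: identical merge heights for all linkages
  du <- matrix(6, 4, 4)
  du[1, 2] <- du[2, 1] <- 2
  du[3, 4] <- du[4, 3] <- 3
  diag(du) <- 0
  dimnames(du) <- list(letters[1:4], letters[1:4])
  hts <- lapply(c("single", "complete", "average"),
                function(l) hierarchical_cluster(du, l)$heights)
  expect_equal(hts[[1]], hts[[2]])
  expect_equal(hts[[1]], hts[[3]])
  expect_equal(hts[[1]], c(2, 3, 6))
})

test_that("clustering matches stats::hclust cophenetic structure", {
  ds <- random_dataset(30, 8, seed = 67)
  D <- dissimilarity_matrix(ds)
  for (linkage in c("single", "complete", "average")) {
    ours <- hierarchical_cluster(D, linkage)
    expect_true(all(diff(ours$heights) >= -1e-12))
    ref <- stats::hclust(as.dist(D$d), method = linkage)
    expect_equal(as.matrix(stats::cophenetic(stats::as.hclust(ours))),
                 as.matrix(stats::cophenetic(ref)), tolerance = 1e-12)
  }
})

test_that("newick export round-trips through ape", {
  skip_if_not_installed("ape")
  # 2-leaf pattern (A:h/2,B:h/2);
  d2 <- matrix(c(0, 0.8, 0.8, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  nk <- dendrogram_to_newick(hierarchical_cluster(d2))
  expect_match(nk, "^\\(A:0.4,B:0.4\\);$")
  # 3-leaf worked example has topology ((A,B),C)
  d3 <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- hierarchical_cluster(d3, "complete")
  phy <- ape::read.tree(text = dendrogram_to_newick(tr))
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  # tree path lengths equal the cophenetic (merge-height) distances
  expect_equal(ape::cophenetic.phylo(phy)[c("A", "B", "C"), c("A", "B", "C")],
               as.matrix(stats::cophenetic(stats::as.hclust(tr)))[
                 c("A", "B", "C"), c("A", "B", "C")], tolerance = 1e-9)
  # random round-trips preserve topology and heights
  for (seed in 1:3) {
    ds <- random_dataset(20, 6, seed = seed)
    tr <- hierarchical_cluster(dissimilarity_matrix(ds))
    phy <- ape::read.tree(text = dendrogram_to_newick(tr))
    ids <- tr$leaf_ids
    expect_equal(ape::cophenetic.phylo(phy)[ids, ids],
                 as.matrix(stats::cophenetic(stats::as.hclust(tr)))[ids, ids],
                 tolerance = 1e-9)
  }
})
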