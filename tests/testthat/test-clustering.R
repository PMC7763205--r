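test_that("row distances are Euclidean and match brute force", {
  v <- matrix(0, 4, 4)
  v[1, 3] <- v[3, 1] <- 3
  v[1, 4] <- v[4, 1] <- 4
  m <- sim_from_matrix(v)
  d <- as.matrix(pairwise_distance(m))
  # row S1 = (0,0,3,4) and row S2 = (0,0,0,0) differ by (3, 4): 3-4-5
  expect_equal(d["S1", "S2"], 5)
  expect_equal(unname(diag(d)), rep(0, 4))

  set.seed(21)
  v5 <- matrix(stats::runif(25), 5, 5); v5 <- v5 + t(v5); diag(v5) <- 0
  m5 <- sim_from_matrix(v5)
  d5 <- as.matrix(pairwise_distance(m5))
  for (i in 1:5) for (j in 1:5) {
    expect_equal(d5[i, j], sqrt(sum((v5[i, ] - v5[j, ])^2)))
  }
  # identical rows -> distance 0
  v5[2, ] <- v5[1, ]; v5[, 2] <- v5[, 1]
  expect_equal(as.matrix(pairwise_distance(sim_from_matrix(v5)))["S1", "S2"], 0)
})

test_that("complete linkage merges nearest pair first and ends at the farthest", {
  d <- matrix(c(0, 1, 2,
                1, 0, 3,
                2, 3, 0), 3, 3, dimnames = list(paste0("S", 1:3), paste0("S", 1:3)))
  dend <- hac_complete(d)
  expect_equal(dend$height, c(1, 3))   # merge {S1,S2} at 1, then all at max = 3

  d2 <- matrix(c(0, 2.5, 2.5, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(hac_complete(d2)$height, 2.5)

  asym <- d; asym[1, 2] <- 9
  expect_error(hac_complete(asym), "symmetric")
  bad_diag <- d; diag(bad_diag) <- 1
  expect_error(hac_complete(bad_diag), "zero diagonal")
})

test_that("merge heights match the naive O(N^3) re-scan oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(4:12, 1)
    d <- random_dist_matrix(n)
    dend <- hac_complete(d)
    expect_equal(dend$height, naive_complete_linkage_heights(d), tolerance = 1e-12)
    expect_true(all(diff(dend$height) >= 0))   # linkage monotonicity
  }
})

test_that("the partition is invariant to subject order for tie-free inputs", {
  set.seed(99)
  d <- random_dist_matrix(10)
  dend <- hac_complete(d)
  base <- cut_tree(dend, k = 3)
  perm <- sample(10)
  dp <- d[perm, perm]
  permuted <- cut_tree(hac_complete(dp), k = 3)[names(base)]
  expect_equal(mclust::adjustedRandIndex(base, permuted), 1)
})

test_that("cut by k spans singletons to one group; depth cuts the root frontier", {
  set.seed(5)
  d <- random_dist_matrix(8)
  dend <- hac_complete(d)
  expect_equal(length(unique(cut_tree(dend, k = 1))), 1)
  expect_equal(length(unique(cut_tree(dend, k = 8))), 8)
  expect_error(cut_tree(dend, k = 0), "1..N")
  expect_error(cut_tree(dend, k = 9), "1..N")
  expect_error(cut_tree(dend, k = 2, depth = 2), "exactly one")

  a1 <- cut_tree(dend, depth = 1)
  expect_equal(length(unique(a1)), 2)
  a3 <- cut_tree(dend, depth = 3)
  expect_lte(length(unique(a3)), 8)
  expect_named(a3)
  # the depth frontier refines the k=2 cut
  tab <- table(a1[names(a3)], a3)
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("clusters are labeled by descending density factor with a mixed flag", {
  # block-diagonal similarity with known block means 1.4, 1.0, 0.7, ~0.001
  sizes <- c(3, 3, 3, 3)
  vals <- c(1.4, 1.0, 0.7, 0.001)
  n <- sum(sizes)
  v <- matrix(0, n, n)
  start <- cumsum(c(1, sizes))
  for (b in 1:4) {
    idx <- start[b]:(start[b + 1] - 1)
    v[idx, idx] <- vals[b]
  }
  diag(v) <- 0
  m <- sim_from_matrix(v, labels = sprintf("S%02d", 1:n))
  assignment <- stats::setNames(rep(1:4, sizes), m$labels)
  model <- label_clusters(assignment, m, mixed_df_threshold = 0.01)
  expect_equal(names(model$density_factors), c("A", "B", "C", "D"))
  expect_equal(unname(model$density_factors), vals, tolerance = 1e-12)
  expect_equal(model$mixed_label, "D")
  expect_equal(unname(model$sizes), sizes)
  expect_setequal(cluster_members(model, "A"), m$labels[1:3])

  single <- label_clusters(stats::setNames(rep(1, n), m$labels), m)
  expect_equal(names(single$density_factors), "A")
  expect_length(single$mixed_label, 0)
})

test_that("equal-DF ties are broken by the smallest subject id", {
  v <- matrix(0, 4, 4)
  v[1, 2] <- v[2, 1] <- 1
  v[3, 4] <- v[4, 3] <- 1
  m <- sim_from_matrix(v, labels = c("S3", "S4", "S1", "S2"))
  assignment <- stats::setNames(c(1, 1, 2, 2), m$labels)
  model <- label_clusters(assignment, m)
  expect_equal(unname(model$assignment[c("S1", "S2")]), c("A", "A"))
  expect_equal(unname(model$assignment[c("S3", "S4")]), c("B", "B"))
})

test_that("source overlap report flags single-source clusters", {
  ev <- dplyr::bind_rows(
    events_from_genes(list(P1 = "A", P2 = "B"), source_ref = "paper_1"),
    events_from_genes(list(P3 = "C"), source_ref = "paper_2"),
    events_from_genes(list(P4 = "D"), source_ref = "paper_3")
  )
  co <- dedup_events(ev)
  m <- build_similarity(co)
  model <- label_clusters(stats::setNames(c(1, 1, 2, 2), c("P1", "P2", "P3", "P4")), m)
  rep_tab <- source_overlap_report(model, ev)
  expect_equal(nrow(rep_tab), 2)
  one_source <- rep_tab[rep_tab$n_sources == 1, ]
  expect_equal(one_source$n_subjects, 2)
  expect_true(one_source$single_source)
  expect_false(rep_tab$single_source[rep_tab$n_sources == 2])
})

test_that("dendrograms export to Newick with all leaves", {
  set.seed(4)
  d <- random_dist_matrix(6)
  dend <- hac_complete(d)
  path <- file.path(withr::local_tempdir(), "dend.nwk")
  write_dendrogram_newick(dend, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(d))
  expect_setequal(leaf_order(dend), rownames(d))
})
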