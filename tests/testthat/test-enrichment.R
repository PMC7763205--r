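test_that("two-column TSV annotations load with set semantics", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ann.tsv")
  writeLines(c("T1\tgeneA", "T1\tgeneB", "T2\tgeneC", "T1\tGENEA"), path)
  ann <- load_annotation(path, format = "tsv2col")
  expect_length(ann$terms, 2)
  expect_setequal(ann$terms$T1, c("GENEA", "GENEB"))   # duplicate counted once
  expect_setequal(ann$background, c("GENEA", "GENEB", "GENEC"))

  expect_error(load_annotation(path, format = "obo"))
  writeLines(character(0), file.path(dir, "empty.tsv"))
  expect_error(load_annotation(file.path(dir, "empty.tsv")), "")
})

test_that("GAF rows with a NOT qualifier are skipped", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ann.gaf")
  writeLines(c(
    "!gaf-version: 2.2",
    paste("DB", "ID1", "GeneA", "involved_in", "GO:0001", "REF", "IDA", "", "P",
          "", "", "protein", "taxon:9606", "20200101", "DB", sep = "\t"),
    paste("DB", "ID2", "GeneB", "NOT|involved_in", "GO:0001", "REF", "IDA", "", "P",
          "", "", "protein", "taxon:9606", "20200101", "DB", sep = "\t"),
    paste("DB", "ID3", "GeneC", "enables", "GO:0002", "REF", "IDA", "", "P",
          "", "", "protein", "taxon:9606", "20200101", "DB", sep = "\t")
  ), path)
  ann <- load_annotation(path, format = "gaf")
  expect_setequal(ann$terms[["GO:0001"]], "GENEA")     # NOT row excluded
  expect_setequal(ann$terms[["GO:0002"]], "GENEC")
})

test_that("fold enrichment is observed over expected", {
  bg <- paste0("G", 1:100)
  ann <- annotation_set(list(T1 = bg[1:10]), background = bg)
  query <- c(bg[1:5], bg[50:54])   # 10 genes, 5 in the term
  row <- fisher_enrich(query, ann)
  expect_equal(row$k_obs, 5)
  expect_equal(row$expected, 10 * 10 / 100)
  expect_equal(row$fold_enrichment, 5)
  expect_equal(row$p_raw, fisher_two_sided_oracle(5, 10, 10, 100), tolerance = 1e-10)

  # k_obs equal to expectation -> FE exactly 1
  ann2 <- annotation_set(list(T1 = bg[1:50]), background = bg)
  row2 <- fisher_enrich(c(bg[1], bg[51]), ann2)
  expect_equal(row2$fold_enrichment, 1)

  # duplicated query genes do not change FE (set semantics)
  row3 <- fisher_enrich(c(query, query[1]), ann)
  expect_equal(row3$fold_enrichment, row$fold_enrichment)
})

test_that("query genes outside the background are dropped with a count", {
  bg <- paste0("G", 1:20)
  ann <- annotation_set(list(T1 = bg[1:5]), background = bg)
  res <- fisher_enrich(c(bg[1:3], "NOT_A_GENE"), ann)
  expect_equal(attr(res, "n_dropped"), 1)
  expect_equal(res$n_list, 3)
  expect_error(fisher_enrich(c("X1", "X2"), ann), "background")
})

test_that("Fisher p-values match exhaustive hypergeometric summation", {
  set.seed(101)
  for (rep in 1:60) {
    n_bg <- sample(10:60, 1)
    k_term <- sample(1:(n_bg - 1), 1)
    n_list <- sample(1:(n_bg - 1), 1)
    bg <- paste0("G", seq_len(n_bg))
    term_genes <- sample(bg, k_term)
    query <- sample(bg, n_list)
    ann <- annotation_set(list(T = term_genes), background = bg)
    k_obs <- length(intersect(query, term_genes))
    two <- fisher_enrich(query, ann, sidedness = "two_sided")$p_raw
    expect_equal(two, fisher_two_sided_oracle(k_obs, k_term, n_list, n_bg),
                 tolerance = 1e-9)
    gr <- fisher_enrich(query, ann, sidedness = "greater")$p_raw
    expect_equal(gr, fisher_greater_oracle(k_obs, k_term, n_list, n_bg),
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment matches hand-computed values and its defining formula", {
  expect_equal(bh_fdr(0.03), 0.03)                       # m = 1 identity
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))         # equal ps unchanged
  expect_error(bh_fdr(c(0.1, 1.5)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, -0.1)), "\\[0, 1\\]")

  set.seed(55)
  for (rep in 1:10) {
    p <- stats::runif(sample(2:40, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))                            # adjusted >= raw
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))              # monotone on sorted ps
  }
})

test_that("ranking filters strictly on FDR, optionally on FE, and tolerates empties", {
  rows <- tibble::tibble(
    term_id = c("T1", "T2", "T3", "T4"),
    name = term_id, n_list = 10L, k_obs = c(5L, 4L, 3L, 0L),
    K_term = 10L, N_bg = 100L, expected = 1,
    fold_enrichment = c(5, 1.2, 3, 0),
    p_raw = c(0.001, 0.001, 0.001, 1),
    p_fdr = c(0.004, 0.004, 0.005, 1)
  )
  out <- rank_and_filter(rows, fdr_max = 0.005)
  expect_setequal(out$term_id, c("T1", "T2"))             # 0.005 is excluded, strict
  expect_equal(out$term_id, c("T1", "T2"))                # FE descending
  out2 <- rank_and_filter(rows, fdr_max = 0.01, fe_min = 1.5)
  expect_false("T2" %in% out2$term_id)                    # FE 1.2 dropped
  expect_false("T4" %in% rank_and_filter(rows, fdr_max = 2)$term_id)  # k_obs 0 never ranked
  expect_equal(nrow(rank_and_filter(rows[0, ])), 0)
})

test_that("the pipeline returns one table per list and empties for disjoint lists", {
  bg <- paste0("G", 1:60)
  ann <- annotation_set(list(T1 = bg[1:10], T2 = bg[11:20]), background = bg)
  lists <- list(hits = bg[1:8], nothing = c("ZZZ1", "ZZZ2"))
  res <- enrich_pipeline(lists, ann, fdr_max = 0.05)
  expect_named(res, c("hits", "nothing"))
  expect_equal(res$hits$term_id, "T1")
  expect_equal(nrow(res$nothing), 0)
})

test_that("type-I error is calibrated at nominal alpha under the null", {
  set.seed(77)
  bg <- paste0("G", 1:400)
  ann <- annotation_set(
    stats::setNames(lapply(1:25, function(i) sample(bg, 20)), paste0("T", 1:25)),
    background = bg)
  n_lists <- 120
  p_all <- unlist(lapply(seq_len(n_lists), function(i) {
    fisher_enrich(sample(bg, 30), ann)$p_raw
  }))
  frac <- mean(p_all < 0.05)
  # Fisher on discrete tables is conservative: at or below alpha, not above
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / length(p_all)))
})
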