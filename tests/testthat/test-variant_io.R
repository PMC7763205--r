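test_that("read_events parses rows, normalizes sequencing types, tolerates blanks", {
  path <- write_event_csv(c(
    varicarta_header,
    "P1,Shank3,22,51113070,A,G,nonsynonymous SNV,whole genome sequencing,de novo,0.001,25.1,paper_1",
    "P1,NRXN1,2,50145643,C,T,synonymous SNV,targeted sequencing,de novo,,,paper_1",
    "P2,CHD8,14,21853353,G,A,stopgain,exome sequencing,inherited,,12,paper_2"
  ))
  ev <- read_events(path)
  expect_equal(nrow(ev), 3)
  expect_equal(length(unique(ev$subject_id)), 2)
  expect_equal(ev$sequencing_type, c("whole_genome", "targeted", "exome"))
  expect_equal(ev$gene_symbol, c("SHANK3", "NRXN1", "CHD8"))
  expect_true(is.na(ev$exac_af[2]))           # empty cell -> absent, no error
  expect_equal(ev$inheritance, c("de_novo", "de_novo", "inherited"))
  expect_equal(attr(ev, "n_rejected"), 0)
})

test_that("read_events rejects rows missing subject/gene and names missing columns", {
  path <- write_event_csv(c(
    varicarta_header,
    "P1,GENE1,1,100,A,G,SNV,whole genome sequencing,de novo,,,p1",
    ",GENE2,1,200,A,G,SNV,whole genome sequencing,de novo,,,p1",
    "P3,,1,300,A,G,SNV,whole genome sequencing,de novo,,,p1"
  ))
  expect_message(ev <- read_events(path), "rejected 2")
  expect_equal(nrow(ev), 1)
  expect_equal(attr(ev, "n_rejected"), 2)

  path2 <- write_event_csv(c("Subject id,Gene Symbol", "P1,GENE1"))
  expect_error(read_events(path2), "sequencing_type")
})

test_that("unparseable numeric fields become missing with a warning", {
  path <- write_event_csv(c(
    varicarta_header,
    "P1,GENE1,1,not_a_number,A,G,SNV,whole genome sequencing,de novo,abc,xyz,p1"
  ))
  expect_warning(expect_warning(expect_warning(
    ev <- read_events(path), "position"), "ExAC"), "CADD")
  expect_true(is.na(ev$pos) && is.na(ev$exac_af) && is.na(ev$cadd_score))
})

test_that("dedup collapses events reported by several publications", {
  ev <- dplyr::bind_rows(
    events_from_genes(list(P1 = "GENE1"), source_ref = "paper_1"),
    events_from_genes(list(P1 = "GENE1"), source_ref = "paper_2"),
    events_from_genes(list(P2 = "GENE1"), source_ref = "paper_1")
  )
  ev$chrom <- "1"; ev$pos <- 100; ev$ref <- "A"; ev$alt <- "G"
  co <- dedup_events(ev)
  expect_equal(co$stats$total_events, 3)
  expect_equal(co$stats$unique_variants, 2)   # same variant in P2 counts separately
  expect_equal(co$stats$duplicates_removed, 1)
  expect_equal(sort(co$subjects), c("P1", "P2"))
})

test_that("dedup key falls back to gene/category when coordinates are absent", {
  ev <- events_from_genes(list(P1 = c("GENE1", "GENE1", "GENE2")))
  co <- dedup_events(ev)
  expect_equal(co$stats$unique_variants, 2)
  expect_setequal(co$genes_by_subject$P1, c("GENE1", "GENE2"))
})

test_that("dedup is idempotent and the empty table yields an empty cohort", {
  ev <- events_from_genes(list(P1 = c("A", "B"), P2 = c("B", "C")))
  co1 <- dedup_events(ev)
  co2 <- dedup_events(co1$events[, names(ev)])
  expect_equal(co2$variants_by_subject, co1$variants_by_subject)
  expect_equal(co2$stats$duplicates_removed, 0)

  empty <- dedup_events(ev[0, ])
  expect_equal(length(empty$subjects), 0)
  expect_equal(empty$stats$unique_variants, 0)
})

test_that("genes_by_subject is the gene projection of variants_by_subject", {
  sim <- generate_cohort(synthetic_config(seed = 11, cluster_sizes = c(5, 5, 5),
                                          n_mixed = 3))
  co <- dedup_events(sim$events)
  for (s in co$subjects) {
    ev_s <- co$events[co$events$subject_id == s, ]
    expect_setequal(co$genes_by_subject[[s]], unique(ev_s$gene_symbol))
    expect_setequal(co$variants_by_subject[[s]], unique(ev_s$variant_key))
  }
})

test_that("sequencing filter keeps only requested types and counts removals", {
  ev <- events_from_genes(list(P1 = paste0("G", 1:10)))
  ev$sequencing_type <- c(rep("whole_genome", 6), rep("exome", 2), rep("targeted", 2))
  kept <- filter_by_sequencing(ev, keep = c("whole_genome", "exome"))
  expect_equal(nrow(kept), 8)
  expect_equal(attr(kept, "n_removed"), 2)

  all_kept <- filter_by_sequencing(ev, keep = c("whole_genome", "exome", "targeted"))
  expect_equal(nrow(all_kept), 10)

  expect_error(filter_by_sequencing(ev, keep = character(0)), "non-empty")
  expect_error(filter_by_sequencing(ev, keep = "nanopore"), "unknown")
})

test_that("ExAC filter uses a strict bound and handles unscored events", {
  ev <- events_from_genes(list(P1 = c("G1", "G2", "G3")))
  ev$exac_af <- c(0.04, 0.05, NA)
  expect_equal(nrow(filter_by_exac(ev, 0.05)), 1)                       # strict <
  expect_equal(nrow(filter_by_exac(ev, 0.01)), 0)
  expect_equal(nrow(filter_by_exac(ev, 0.05, require_score = FALSE)), 2)
  expect_error(filter_by_exac(ev, 0), "max_af")
  expect_error(filter_by_exac(ev, 1.2), "max_af")
})

test_that("CADD bins are left-closed right-open with an unscored bucket", {
  ev <- events_from_genes(list(P1 = paste0("G", 1:5)))
  ev$cadd_score <- c(5, 15, 42, 10, NA)
  bins <- bin_by_cadd(ev)
  expect_named(bins, c("<10", "10-19", "20-29", "30-39", ">=40", "unscored"))
  expect_equal(nrow(bins[["<10"]]), 1)
  expect_equal(nrow(bins[["10-19"]]), 2)      # score exactly 10 goes up
  expect_equal(nrow(bins[[">=40"]]), 1)
  expect_equal(nrow(bins$unscored), 1)
  expect_equal(sum(vapply(bins, nrow, integer(1))), nrow(ev))  # conservation

  all_na <- ev; all_na$cadd_score <- NA_real_
  expect_equal(nrow(bin_by_cadd(all_na)$unscored), 5)
  expect_error(bin_by_cadd(ev, edges = c(10, 10, 20)), "strictly increasing")
})

test_that("filters commute with each other on the surviving set", {
  set.seed(301)
  sim <- generate_cohort(synthetic_config(seed = 301, cluster_sizes = c(8, 8, 8),
                                          n_mixed = 4, exac_annotated_rate = 0.3,
                                          cadd_annotated_rate = 0.3))
  ev <- sim$events
  a <- filter_by_exac(filter_by_sequencing(ev, "whole_genome"), 0.05)
  b <- filter_by_sequencing(filter_by_exac(ev, 0.05), "whole_genome")
  expect_equal(a[order(a$subject_id, a$pos), ]$pos, b[order(b$subject_id, b$pos), ]$pos)
  expect_equal(nrow(a), nrow(b))
})
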