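#!/usr/bin/env Rscript
# Over-representation analysis of every Venn partition's gene list against
# the cohort's term annotation (Fisher's exact test, FDR < 0.005 two-tailed,
# ranked by fold enrichment), plus the score-filtered reruns of the
# three-cluster intersection: ExAC allele frequency < 0.05 and < 0.01, and
# CADD deleteriousness bins.

suppressMessages(library(patsim))

cohort_dir <- "results/cohorts/medium"
part_dir <- "results/partitions"
out_dir <- "results/enrichment"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

if (!dir.exists(part_dir)) {
  stop("partition outputs not found: run analysis/03_partitions.R first")
}

ann <- load_annotation(file.path(cohort_dir, "annotation.tsv"), format = "tsv2col")
print(ann)

part_files <- list.files(part_dir, pattern = "_genes\\.txt$", full.names = TRUE)
gene_lists <- stats::setNames(lapply(part_files, readLines),
                              sub("_genes\\.txt$", "", basename(part_files)))
tables <- enrich_pipeline(gene_lists, ann, fdr_max = 0.005)
for (nm in names(tables)) {
  tab <- tables[[nm]]
  cat(sprintf("partition %-7s: %3d genes, %2d significant terms", nm,
              length(gene_lists[[nm]]), nrow(tab)))
  if (nrow(tab) > 0) {
    cat(sprintf(" (top: %s, FE %.1f, FDR %.2g)",
                tab$term_id[1], tab$fold_enrichment[1], tab$p_fdr[1]))
  }
  cat("\n")
  readr::write_tsv(tab, file.path(out_dir, paste0(nm, "_enrichment.tsv")),
                   progress = FALSE)
}

## score-filtered reruns on the three-cluster intersection
events <- filter_by_sequencing(read_events(file.path(cohort_dir, "events.csv")),
                               keep = c("whole_genome", "exome"))
co <- dedup_events(events)
abc_keys <- local({
  fit <- cluster_cohort(co, k = 4, mixed_df_threshold = 0.1)
  dense <- setdiff(names(fit$model$density_factors), fit$model$mixed_label)[1:3]
  sets <- lapply(dense, function(l) shared_variants(co, cluster_members(fit$model, l)))
  venn_partitions(sets)$ABC
})
abc_events <- co$events[co$events$variant_key %in% abc_keys, ]

enrich_genes <- function(genes, label) {
  if (length(genes) == 0 || sum(toupper(genes) %in% ann$background) == 0) {
    cat(sprintf("%-28s: no genes in background, skipped\n", label))
    return(invisible(NULL))
  }
  tab <- rank_and_filter(fisher_enrich(genes, ann), fdr_max = 0.005)
  cat(sprintf("%-28s: %3d genes -> %2d significant terms\n",
              label, length(unique(toupper(genes))), nrow(tab)))
  readr::write_tsv(tab, file.path(out_dir, paste0(label, ".tsv")), progress = FALSE)
}

for (af in c(0.05, 0.01)) {
  flt <- filter_by_exac(abc_events, max_af = af)
  enrich_genes(unique(flt$gene_symbol), sprintf("ABC_exac_lt_%g", af))
}
bins <- bin_by_cadd(abc_events)
for (b in setdiff(names(bins), "unscored")) {
  enrich_genes(unique(bins[[b]]$gene_symbol),
               paste0("ABC_cadd_", gsub("[<>=]", "", b)))
}
cat("enrichment tables written under", out_dir, "\n")
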