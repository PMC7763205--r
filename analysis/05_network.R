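#!/usr/bin/env Rscript
# Interaction-network view of the dense clusters' frequent genes: genes
# carried by >= 50 subjects are scored for observed vs expected interaction
# edges against the cohort's background network, with a seeded Monte-Carlo
# null of uniform same-size gene samples.

suppressMessages(library(patsim))

cohort_dir <- "results/cohorts/medium"
out_dir <- "results/network"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

events <- filter_by_sequencing(read_events(file.path(cohort_dir, "events.csv")),
                               keep = c("whole_genome", "exome"))
co <- dedup_events(events)
fit <- cluster_cohort(co, k = 4, mixed_df_threshold = 0.1)
dense <- setdiff(names(fit$model$density_factors), fit$model$mixed_label)[1:3]
members <- unlist(lapply(dense, cluster_members, model = fit$model))

genes <- frequent_genes(co, members = members, min_patients = 50)
cat(sprintf("%d genes present in at least 50 of the %d dense-cluster subjects\n",
            length(genes), length(members)))

graph <- read_edge_list(file.path(cohort_dir, "edges.tsv"))
print(graph)
res <- edge_ratio(genes, graph, n_random = 1000, seed = 404)
cat(sprintf(
  "nodes: %d, observed edges: %d, expected: %.1f, ratio: %.1f, empirical p: %.3g\n",
  res$n_genes, res$observed, res$expected, res$ratio, res$p_empirical))

jsonlite::write_json(res, file.path(out_dir, "edge_ratio.json"),
                     auto_unbox = TRUE, pretty = TRUE)
cat("network artifacts written under", out_dir, "\n")
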