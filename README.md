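# patsim — patient similarity clustering and enrichment for variant cohorts

Literature-aggregated variant catalogues (VariCarta-style tables for autism
spectrum disorder cohorts) record one row per subject × variant event: the
affected gene, coordinates, variant category, sequencing type, inheritance
status, and sparse ExAC allele-frequency / CADD deleteriousness annotation.
`patsim` turns such a table into genetically defined patient subgroups and the
biological processes their shared variants point to:

1. **Patient similarity.** For subjects *i*, *j* with affected-gene sets
   *G<sub>i</sub>*, *G<sub>j</sub>*, the similarity matrix is
   *a<sub>ij</sub>* = |*G<sub>i</sub>* ∩ *G<sub>j</sub>*|, log2-transformed
   (with T(0) = 0) to compress the heavy tail.
2. **Clustering.** Complete-linkage (farthest-point) hierarchical
   agglomerative clustering on Euclidean distances between matrix rows;
   the tree is cut into *k* groups, and clusters are labeled A, B, C, … by
   descending *density factor* (DF = mean within-block similarity). A
   near-zero-DF cluster is the "mixed group": subjects who share essentially
   nothing with anyone.
3. **Shared variants and Venn partitions.** Each cluster's variants carried
   by ≥ 2 members are intersected across the three dense clusters into seven
   disjoint partitions (A-only … ABC), each analyzed separately.
4. **Over-representation.** Per annotation term, Fisher's exact test
   (two-tailed, FDR < 0.005) with fold enrichment
   FE = k<sub>obs</sub> / (n<sub>list</sub> · K<sub>term</sub> / N<sub>bg</sub>),
   ranked by FE as the effect size; plus ExAC- and CADD-stratified reruns.
5. **Network view.** Observed vs expected interaction edges among frequently
   carried genes, against a seeded uniform Monte-Carlo null.

A first-class synthetic cohort generator plants clusters, enriched terms and
dense network modules with known truth labels, so every stage is testable
end to end without any external download.

## Worked example

```r
library(patsim)

sim <- generate_cohort(synthetic_config(seed = 42))       # 3×30 + 10 mixed subjects
ev  <- filter_by_sequencing(sim$events, c("whole_genome", "exome"))
co  <- dedup_events(ev)
co
#> <cohort> 100 subjects, 6755 unique subject-variant pairs (874 duplicate events removed)

fit <- cluster_cohort(co, k = 4, mixed_df_threshold = 0.1)
fit$model
#> <cluster_model>
#>   A: 30 subjects, DF = 2.780
#>   B: 30 subjects, DF = 2.711
#>   C: 30 subjects, DF = 2.673
#>   D (mixed): 10 subjects, DF = 0.022
evaluate_recovery(sim, fit$model)$ari
#> [1] 1
```

The three planted clusters come back with density factors near 2.7 while the
mixed group's DF is two orders of magnitude lower, and the recovered
partition matches the planted one exactly (adjusted Rand index 1). Extracting
each cluster's shared variants, intersecting them, and testing the
three-cluster intersection against the cohort's annotation ranks the planted
shared-core terms on top (fold enrichments in the hundreds at FDR ≪ 0.005)
with no noise term passing the filter.

## Analysis workflow

The numbered scripts under `analysis/` run the full study on generated
cohorts and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # small (60) and medium (600-subject) cohorts
Rscript analysis/02_cluster.R     # similarity -> HAC -> k=4 cut -> DF labels
Rscript analysis/03_partitions.R  # shared variants, 7-way Venn, gene lists
Rscript analysis/04_enrich.R      # per-partition + ExAC/CADD-filtered enrichment
Rscript analysis/05_network.R     # frequent genes, observed/expected edges
```

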