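---
title: "Methods: gene-sharing patient similarity, cluster density, and shared-variant enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-sharing patient similarity, cluster density, and shared-variant enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patsim)
```

## The model

`patsim` analyzes literature-aggregated variant catalogues in which each row
is a subject × variant event. The pipeline's object of interest is not any
single variant but the *pattern of gene sharing between patients*: subjects
whose variants repeatedly hit the same genes are taken to be genetically
related, and the biological processes over-represented among the genes they
share are read as candidate disease mechanisms.

Formally, with $G_i$ the set of genes affected by at least one variant in
subject $i$, the similarity matrix is

$$a_{ij} = |G_i \cap G_j|, \qquad i \neq j,$$

log2-transformed elementwise with $T(0) = 0$ so the matrix stays finite and
non-negative. Subjects are then clustered by complete-linkage hierarchical
agglomerative clustering — inter-cluster distance is the *maximum* cross-pair
distance, the farthest-point rule, chosen to maximize separation between
groups — on the Euclidean distances between matrix rows. Each cluster is
summarized by its **density factor** (DF), the mean of all off-diagonal
similarity cells in its block, and clusters are labeled A, B, C, … from
densest down. A cluster whose DF is essentially zero is the **mixed group**:
subjects genetically uncorrelated with everyone.

Key modeling assumptions, each inherited from the catalogue format:

- *Gene-symbol granularity.* Similarity counts shared genes, not shared
  alleles; two different variants of the same gene contribute the same gene
  to the intersection.
- *Deduplicated events.* The same variant event reported by several
  publications for the same subject counts once. The deduplication key is
  coordinate identity (`chrom:pos:ref:alt`) when coordinates are present,
  else `gene|category|event label` — the catalogue's own identity notion is
  not published, so both are supported.
- *Whole-genome focus.* Targeted-sequencing records (~2 % of events) are
  excluded by default: targeted panels only interrogate pre-selected genes
  and would bias per-subject gene sets.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `k` (cut) | 4 | groups after cutting the tree: three dense clusters + mixed group |
| `mixed_df_threshold` | 0.01 | absolute DF below which a cluster is labeled mixed |
| `min_subjects` | 2 | carriers within a cluster for a variant to count as shared |
| `fdr_max` | 0.005 | strict two-tailed FDR cutoff for enrichment |
| `fe_min` | off (1.5 typical) | optional fold-enrichment floor for reported tables |
| `min_patients` | 50 | carriers for a gene to enter the network analysis |
| `n_random` | 1000 | Monte-Carlo samples for the expected edge count |

The tree cut is by *k* rather than by depth: a depth-3 frontier of a binary
dendrogram can yield anywhere from 2 to 8 groups depending on tree shape, so
"cut into k groups" is the reproducible primitive, with `cut_tree(depth =)`
available for exploration. `mixed_df_threshold` is an absolute DF on the
log2 scale; at catalogue scale mixed-group DFs are ~0.001 so 0.01 is a safe
default, while small synthetic cohorts (where even background collisions
give DF ≈ 0.02) warrant ~0.1.

## Enrichment statistics

Per term, the $2\times2$ table
$[k_{obs},\; n_{list}-k_{obs};\; K_{term}-k_{obs},\; N_{bg}-n_{list}-K_{term}+k_{obs}]$
is tested with Fisher's exact test. Two-sided p-values follow the standard
convention (sum of the probabilities of all tables no more probable than the
observed one); one-sided `greater` is available since over-representation is
the scientific question. Benjamini–Hochberg adjustment is applied across all
tested terms. Because raw and adjusted p-values both shrink mechanically
with list size, significant terms are *ranked by fold enrichment*
$FE = k_{obs} / (n_{list} K_{term} / N_{bg})$, an effect-size ordering.
Terms with $k_{obs}=0$ are reported with FE 0 and never ranked. No term-size
floor is applied by default and no ontology-graph propagation is performed:
the annotation file is taken as given.

The network stage replaces a curated-database analytic null with a **seeded
uniform Monte-Carlo null**: expected edge counts are the mean over `n_random`
same-size uniform node samples, and the empirical one-sided p-value is the
add-one-corrected exceedance fraction. This null is degree-agnostic — it
ignores that frequently carried genes may be hubs — which is the price of
having no service dependency; ratios from it are comparable across runs with
the same seed but not directly to degree-aware service p-values.

## What the synthetic generator emulates

`synthetic_config()` defaults describe the smallest cohort on which the full
pipeline is exercised: 3 planted clusters × 30 subjects + 10 mixed, Poisson
mean 70 variants per subject, module pools of 250 genes sampled with
probability 0.6, a 50-gene shared core sampled at 0.12, and a background of
20 000 genes (human protein-coding scale — large enough that background
collisions between subjects are rare and the mixed group's DF stays near
zero, two orders of magnitude below the dense clusters). Each gene carries 2
fixed variant sites so the *same variant* recurs across subjects and
variant-level sharedness is well defined. An occupancy calculation fixes the
shared-core rate: with 30 subjects drawing ~8.4 core variants each over 100
sites, a site is shared by ≥ 2 members of one cluster with probability
≈ 0.7, hence carried into the three-way intersection with probability
≈ 0.36, populating the ABC partition with ~35 variants — enough for its
gene list to recover the planted shared-core terms.

Nuisance structure mirrors a literature-aggregated de novo catalogue:
~10 % duplicate events re-emitted under a second source publication, 2 %
targeted-sequencing records, 0.3 % inherited variants, ExAC scores on ~0.9 %
of events (with 2.5 % of scored values above 0.01 and 0.7 % above 0.05) and
CADD scores on ~1.3 %.

What the generator does **not** emulate — and hence what passing tests do
not show about real catalogues: realistic mutation-rate heterogeneity and
gene length effects, linkage between variants, meaningful genomic
coordinates, overlapping cluster membership, ontology-graph structure among
terms, and degree-correlated interaction networks. Recovery results on
synthetic cohorts demonstrate algorithmic correctness, not biological
validity at catalogue scale (where cluster sizes are in the hundreds and
per-pair sharing reaches 60+ genes).

## Numerical and design choices

- $T(0)=0$ for the log2 transform, with the side effect that counts 0 and 1
  both map to 0; the matrix range then starts at 0 for "nothing in common",
  matching heatmap conventions. `log2(n+1)` was considered and rejected as
  the default because it shifts every value, not just the degenerate ones.
- The matrix diagonal is fixed at 0 (self-comparison suppressed); the DF of
  a member set averages all off-diagonal ordered pairs, which for a
  symmetric matrix equals the unordered-pair mean.
- Distances are computed on matrix *rows* as feature vectors (clustermap
  semantics for a square input), not by reading the matrix itself as
  distances: two subjects are close when they relate to the whole cohort
  similarly.
- Merge ties in the linkage are resolved by `stats::hclust`'s internal
  order. All correctness checks use continuous random distances where ties
  have probability zero; `hclust` itself is deterministic, so repeated runs
  agree.
- Equal-DF ties in cluster labeling are broken by the smallest subject id in
  the cluster, for reproducible labels.
- Sharedness is assessed at the variant level by default (the stricter
  reading; two subjects hitting different alleles of one gene do not share)
  with `level = "gene"` as the configurable alternative, and gene projection
  happens after partitioning.
- The ExAC filter is strict (`< max_af`) and by default drops unscored
  events, since score-filtered analyses are only meaningful where the score
  was reported; `require_score = FALSE` keeps them.
- CADD bins are left-closed right-open (`10–19` means $[10, 20)$) with an
  explicit `unscored` bucket so binning conserves event counts.
- Fisher p-values are clamped into $[0,1]$ before BH adjustment to absorb
  floating-point overshoot of the exact-test summation.
- Unknown inheritance defaults to de novo for sensitivity splits, since
  de novo events dominate such catalogues (99.7 %); configurable.

## Problem sizes

The shipped tests and the acceptance script run the pipeline at the
100-subject default scale (20 seeds for recovery and planted-term checks),
verify the linkage against a naive $O(N^3)$ re-scan on 200 random instances
of up to 12 points, Fisher's test against exhaustive hypergeometric
summation on 500 random tables with backgrounds up to 60 genes, and
calibrate the null on 1000 random query lists of 300 genes against 10
disjoint 100-gene terms over a 1000-gene background — a table geometry
chosen, by exact hypergeometric calculation, so that the discrete test's
true null rejection rate at $\alpha = 0.05$ sits essentially at nominal. The analysis scripts use
a 600-subject cohort, where the 50-carrier network threshold selects the
planted shared core.

## Known limitations

- The uniform network null understates expected edges for hub-heavy query
  sets; its ratios are not comparable to degree-corrected nulls.
- Fisher's exact test is conservative on small discrete tables; calibration
  at nominal $\alpha$ holds only when expected overlaps are well away
  from 0.
- Complete linkage is sensitive to outliers (a single distant member sets
  the cluster's height); no bootstrap stability assessment is included.
- No variant normalization (left-alignment), liftover, or gene-identifier
  mapping: the event table is trusted as curated.
- With `min_subjects = 2`, shared-variant sets grow with cluster size purely
  combinatorially; comparisons across clusters of very different sizes
  should use the per-partition enrichment, not raw shared counts.
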