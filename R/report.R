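#' Reporting helpers and the end-to-end clustering convenience wrapper
#'
#' @name report
NULL

#' Percentage of a whole
#'
#' The reporting arithmetic used throughout cohort summaries: what percent of
#' `whole` is `part`.
#'
#' @param part,whole Non-negative counts; `whole > 0`.
#' @return `100 * part / whole` (unrounded).
#' @export
percent_of <- function(part, whole) {
  if (whole <= 0) stop("'whole' must be positive", call. = FALSE)
  100 * part / whole
}

#' Summary counts for an event table and its cohort
#'
#' @param events Event tibble (pre-dedup).
#' @param cohort The [cohort] from [dedup_events()].
#' @return Named list of counts and percentages: total events, unique
#'   variants, duplicates removed, percent unique, percent de novo (of
#'   deduplicated events), percent with ExAC / CADD scores, percent targeted
#'   records.
#' @export
cohort_summary <- function(events, cohort) {
  stopifnot(inherits(cohort, "cohort"))
  dedup <- cohort$events
  list(
    total_events = nrow(events),
    unique_variants = cohort$stats$unique_variants,
    duplicates_removed = cohort$stats$duplicates_removed,
    pct_unique = percent_of(cohort$stats$unique_variants, nrow(events)),
    pct_de_novo = percent_of(sum(dedup$inheritance == "de_novo"), nrow(dedup)),
    pct_exac_scored = percent_of(sum(!is.na(dedup$exac_af)), nrow(dedup)),
    pct_cadd_scored = percent_of(sum(!is.na(dedup$cadd_score)), nrow(dedup)),
    pct_targeted_records = percent_of(sum(events$sequencing_type == "targeted"), nrow(events))
  )
}

#' Similarity, clustering and labeling in one call
#'
#' The default path: raw gene-sharing counts, log2 transform, Euclidean row
#' distances, complete-linkage tree, cut into `k` groups, labels ordered by
#' descending density factor with a mixed-group threshold.
#'
#' @param cohort A [cohort] with >= 2 subjects.
#' @param k Number of groups to cut (default 4: three dense clusters plus
#'   the mixed group).
#' @param mixed_df_threshold DF below which a cluster is labeled mixed.
#' @param transform `"log2"` (default) or `"raw"`.
#' @return List with `similarity` (transformed `similarity_matrix`),
#'   `raw_similarity`, `dend` ([stats::hclust]) and `model`
#'   (`cluster_model`).
#' @export
cluster_cohort <- function(cohort, k = 4, mixed_df_threshold = 0.01,
                           transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  raw <- build_similarity(cohort)
  m <- if (transform == "log2") log2_transform(raw) else raw
  dend <- hac_complete(pairwise_distance(m))
  assignment <- cut_tree(dend, k = k)
  model <- label_clusters(assignment, m, mixed_df_threshold = mixed_df_threshold)
  list(similarity = m, raw_similarity = raw, dend = dend, model = model)
}
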