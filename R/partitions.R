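#' Shared-variant sets and their three-way Venn decomposition
#'
#' A cluster's shared-variant set contains the variants carried by at least
#' `min_subjects` distinct members of the cluster. Because clusters partition
#' subjects, not variants, the same variant can be shared within several
#' clusters — intersecting the three dense clusters' shared sets yields seven
#' disjoint Venn partitions (A-only, B-only, C-only, AB, AC, BC, ABC), each
#' of which is analyzed for enrichment separately.
#'
#' @name partitions
NULL

#' Variants shared within a cluster
#'
#' @param cohort A [cohort].
#' @param members Non-empty character vector of subject ids.
#' @param min_subjects Minimum number of distinct carriers within `members`
#'   for a variant to count as shared (>= 2).
#' @param level Count sharing at the `"variant"` key level (default, the
#'   stricter reading) or at the `"gene"` level.
#' @return An object of class `shared_variant_set`: list with `variants`
#'   (shared keys), `genes` (their gene projection) and `n_members`.
#' @export
shared_variants <- function(cohort, members, min_subjects = 2, level = c("variant", "gene")) {
  stopifnot(inherits(cohort, "cohort"))
  level <- match.arg(level)
  if (length(members) == 0) stop("'members' must be non-empty", call. = FALSE)
  if (min_subjects < 2) stop("'min_subjects' must be >= 2", call. = FALSE)
  ev <- cohort$events[cohort$events$subject_id %in% members, , drop = FALSE]
  unit <- if (level == "variant") ev$variant_key else ev$gene_symbol
  carriers <- tapply(ev$subject_id, unit, function(s) length(unique(s)))
  shared_units <- names(carriers)[carriers >= min_subjects]
  if (level == "variant") {
    genes <- unique(ev$gene_symbol[ev$variant_key %in% shared_units])
    variants <- shared_units
  } else {
    genes <- shared_units
    variants <- unique(ev$variant_key[ev$gene_symbol %in% shared_units])
  }
  structure(list(variants = variants, genes = genes, n_members = length(members)),
            class = "shared_variant_set")
}

#' @export
print.shared_variant_set <- function(x, ...) {
  cat(sprintf("<shared_variant_set> %d variants over %d genes (%d cluster members)\n",
              length(x$variants), length(x$genes), x$n_members))
  invisible(x)
}

#' Seven-way Venn partition of three shared-variant sets
#'
#' @param sets Named list of exactly three character vectors (or
#'   `shared_variant_set`s); names default to `A`, `B`, `C`.
#' @return Named list of class `venn_partitions` with elements `A_only`,
#'   `B_only`, `C_only`, `AB`, `AC`, `BC`, `ABC` — pairwise disjoint, their
#'   union equal to the union of the inputs.
#' @export
venn_partitions <- function(sets) {
  if (length(sets) != 3) stop("exactly three sets are required", call. = FALSE)
  sets <- lapply(sets, function(s) if (inherits(s, "shared_variant_set")) s$variants else s)
  if (is.null(names(sets)) || any(names(sets) == "")) names(sets) <- c("A", "B", "C")
  a <- unique(sets[[1]]); b <- unique(sets[[2]]); c_ <- unique(sets[[3]])
  universe <- unique(c(a, b, c_))
  in_a <- universe %in% a; in_b <- universe %in% b; in_c <- universe %in% c_
  out <- list(
    A_only = universe[in_a & !in_b & !in_c],
    B_only = universe[!in_a & in_b & !in_c],
    C_only = universe[!in_a & !in_b & in_c],
    AB     = universe[in_a & in_b & !in_c],
    AC     = universe[in_a & !in_b & in_c],
    BC     = universe[!in_a & in_b & in_c],
    ABC    = universe[in_a & in_b & in_c]
  )
  class(out) <- "venn_partitions"
  out
}

#' @export
print.venn_partitions <- function(x, ...) {
  counts <- lengths(unclass(x))
  cat(sprintf("<venn_partitions> total %d\n", sum(counts)))
  print(counts)
  invisible(x)
}

#' Percentage share of each Venn partition
#'
#' @param counts Named non-negative counts per partition (e.g.
#'   `lengths(venn_partitions(...))`), with positive total.
#' @return Tibble with `partition`, `count`, `share` (unrounded percent) and
#'   `share_pct` (rounded to one decimal, the reporting convention).
#' @export
partition_share <- function(counts) {
  counts <- unlist(counts)
  if (is.null(names(counts))) stop("'counts' must be named", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive", call. = FALSE)
  share <- 100 * counts / total
  tibble::tibble(partition = names(counts), count = as.integer(counts),
                 share = unname(share), share_pct = round(unname(share), 1))
}

#' Write per-partition gene lists
#'
#' One plain-text file per partition (one gene symbol per line — the de facto
#' input format of enrichment tools) plus a JSON of counts.
#'
#' @param parts A `venn_partitions` object over variant keys.
#' @param cohort The [cohort] (used to project variants onto genes).
#' @param dir Output directory (created if needed).
#' @return Named list of gene vectors per partition, invisibly.
#' @export
write_partition_gene_lists <- function(parts, cohort, dir) {
  stopifnot(inherits(parts, "venn_partitions"), inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  key2gene <- cohort$events[!duplicated(cohort$events$variant_key),
                            c("variant_key", "gene_symbol")]
  gene_lists <- lapply(unclass(parts), function(keys) {
    sort(unique(key2gene$gene_symbol[key2gene$variant_key %in% keys]))
  })
  for (nm in names(gene_lists)) {
    writeLines(gene_lists[[nm]], file.path(dir, paste0(nm, "_genes.txt")))
  }
  jsonlite::write_json(
    list(variant_counts = as.list(lengths(unclass(parts))),
         gene_counts = as.list(lengths(gene_lists))),
    file.path(dir, "partition_counts.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(gene_lists)
}
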