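#' Complete-linkage hierarchical clustering of subjects
#'
#' Subjects are clustered bottom-up on the Euclidean distances between their
#' similarity-matrix rows (each subject's row is its feature vector — the
#' square similarity matrix is treated as an observation matrix, mirroring
#' heatmap/clustermap semantics). The linkage is "complete" (farthest point):
#' the distance between two clusters is the maximum cross-pair distance,
#' which maximizes separation between the resulting groups.
#'
#' @name clustering
NULL

#' Euclidean row distances of a similarity matrix
#'
#' @param m A `similarity_matrix` (typically log2-transformed).
#' @return A [stats::dist] object over subjects.
#' @export
pairwise_distance <- function(m) {
  stopifnot(inherits(m, "similarity_matrix"))
  if (!isSymmetric(unname(m$values))) stop("similarity matrix must be symmetric", call. = FALSE)
  stats::dist(m$values, method = "euclidean")
}

#' Complete-linkage agglomerative clustering
#'
#' @param d A [stats::dist] object, or a symmetric matrix with zero diagonal.
#' @return An [stats::hclust] tree (merge heights are non-decreasing; complete
#'   linkage is monotone).
#' @export
hac_complete <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric", call. = FALSE)
    if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal", call. = FALSE)
    d <- stats::as.dist(d)
  }
  if (!inherits(d, "dist")) stop("'d' must be a dist object or symmetric matrix", call. = FALSE)
  stats::hclust(d, method = "complete")
}

#' Cut a dendrogram into groups
#'
#' Either by `k` (the k groups present after undoing the k-1 highest merges)
#' or by `depth` (the frontier of dendrogram nodes at the given number of
#' levels below the root; leaves stop subdividing, so a depth cut yields at
#' most `2^depth` groups).
#'
#' @param dend An [stats::hclust] tree.
#' @param k Number of groups (1..N), exclusive with `depth`.
#' @param depth Levels below the root (>= 1), exclusive with `k`.
#' @return Integer vector of group codes named by subject id.
#' @export
cut_tree <- function(dend, k = NULL, depth = NULL) {
  stopifnot(inherits(dend, "hclust"))
  n <- length(dend$labels)
  if (is.null(k) == is.null(depth)) stop("supply exactly one of 'k' or 'depth'", call. = FALSE)
  if (!is.null(k)) {
    if (k < 1 || k > n) stop("'k' must be in 1..N", call. = FALSE)
    return(stats::cutree(dend, k = k))
  }
  if (depth < 1) stop("'depth' must be >= 1", call. = FALSE)
  # frontier after `depth` expansions from the root; +i = merge node, -i = leaf
  frontier <- nrow(dend$merge)
  for (step in seq_len(depth)) {
    nxt <- integer(0)
    for (node in frontier) {
      if (node > 0) nxt <- c(nxt, dend$merge[node, ]) else nxt <- c(nxt, node)
    }
    frontier <- nxt
  }
  leaves_under <- function(node) {
    if (node < 0) return(-node)
    unlist(lapply(dend$merge[node, ], leaves_under))
  }
  assignment <- integer(n)
  for (g in seq_along(frontier)) assignment[leaves_under(frontier[g])] <- g
  stats::setNames(assignment, dend$labels)
}

#' Label clusters by descending density factor
#'
#' Clusters are ranked by their density factor (mean within-block similarity)
#' and labeled `A`, `B`, `C`, ... from densest down. Clusters whose DF falls
#' below `mixed_df_threshold` are flagged as the "mixed group": subjects who
#' share essentially no variants with anyone. Singleton clusters get DF 0.
#' Ties in DF are broken by the smallest subject id in the cluster.
#'
#' @param assignment Integer group codes named by subject id (from
#'   [cut_tree()]).
#' @param m The `similarity_matrix` the clustering was computed from.
#' @param mixed_df_threshold DF below which a cluster is called mixed.
#' @return An object of class `cluster_model`: list with `assignment`
#'   (subject id -> label), `density_factors` (label -> DF, descending),
#'   `mixed_label` (labels of mixed clusters, possibly empty), `sizes`.
#' @export
label_clusters <- function(assignment, m, mixed_df_threshold = 0.01) {
  stopifnot(inherits(m, "similarity_matrix"), !is.null(names(assignment)))
  groups <- split(names(assignment), assignment)
  if (length(groups) < 1) stop("need at least one cluster", call. = FALSE)
  dfs <- vapply(groups, function(mem) {
    if (length(mem) < 2) 0 else density_factor(m, mem)
  }, numeric(1))
  first_id <- vapply(groups, function(mem) min(mem), character(1))
  ord <- order(-dfs, first_id)
  labels <- make_cluster_labels(length(groups))
  relabel <- stats::setNames(labels, names(groups)[ord])
  out_assignment <- stats::setNames(unname(relabel[as.character(assignment)]), names(assignment))
  density_factors <- stats::setNames(dfs[ord], labels)
  mixed <- labels[density_factors < mixed_df_threshold]
  structure(
    list(assignment = out_assignment,
         density_factors = density_factors,
         mixed_label = mixed,
         sizes = stats::setNames(lengths(groups)[ord], labels)),
    class = "cluster_model"
  )
}

make_cluster_labels <- function(k) {
  if (k <= 26) return(LETTERS[seq_len(k)])
  paste0(rep(LETTERS, times = ceiling(k / 26))[seq_len(k)],
         rep(seq_len(ceiling(k / 26)), each = 26)[seq_len(k)])
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model>\n")
  for (lab in names(x$density_factors)) {
    cat(sprintf("  %s%s: %d subjects, DF = %.3f\n",
                lab, if (lab %in% x$mixed_label) " (mixed)" else "",
                x$sizes[[lab]], x$density_factors[[lab]]))
  }
  invisible(x)
}

#' Members of one cluster
#' @param model A `cluster_model`.
#' @param label Cluster label, e.g. `"A"`.
#' @return Character vector of subject ids.
#' @export
cluster_members <- function(model, label) {
  stopifnot(inherits(model, "cluster_model"))
  names(model$assignment)[model$assignment == label]
}

#' Source-publication overlap per cluster
#'
#' Checks that no cluster is an artifact of a single source dataset: for each
#' cluster, the distinct source publications contributing its members'
#' events. Clusters fed by a single source are flagged.
#'
#' @param model A `cluster_model`.
#' @param events Event tibble carrying a `source_ref` column.
#' @return Tibble with columns `cluster`, `n_subjects`, `n_sources`,
#'   `sources` (list column), `single_source`.
#' @export
source_overlap_report <- function(model, events) {
  stopifnot(inherits(model, "cluster_model"), "source_ref" %in% names(events))
  labs <- names(model$density_factors)
  rows <- lapply(labs, function(lab) {
    mem <- cluster_members(model, lab)
    src <- sort(unique(events$source_ref[events$subject_id %in% mem & !is.na(events$source_ref)]))
    tibble::tibble(cluster = lab, n_subjects = length(mem),
                   n_sources = length(src), sources = list(src),
                   single_source = length(mem) > 0 && length(src) == 1)
  })
  dplyr::bind_rows(rows)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths derive from the merge heights.
#'
#' @param dend An [stats::hclust] tree.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dend, path) {
  stopifnot(inherits(dend, "hclust"))
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}

#' Leaf order for heatmap display
#'
#' @param dend An [stats::hclust] tree.
#' @return Character vector of subject ids in dendrogram leaf order.
#' @export
leaf_order <- function(dend) {
  stopifnot(inherits(dend, "hclust"))
  dend$labels[dend$order]
}
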