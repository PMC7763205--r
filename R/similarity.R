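#' Patient similarity matrices
#'
#' The similarity between two subjects is the number of genes affected by a
#' variant in both: `a[i,j] = |G_i intersect G_j|`, where `G_i` is subject
#' i's gene set. A log2 transform compresses the heavy-tailed raw counts onto
#' the 0–6 range typical of heatmap display (64 shared genes -> 6).
#'
#' @name similarity
NULL

new_similarity_matrix <- function(values, transform) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            !is.null(rownames(values)), identical(rownames(values), colnames(values)))
  structure(list(labels = rownames(values), values = values, transform = transform),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d subjects, transform = %s, max = %.3g\n",
              nrow(x$values), ncol(x$values), x$transform, max(x$values)))
  invisible(x)
}

#' Build the raw gene-sharing similarity matrix
#'
#' Computes the symmetric subject x subject matrix of shared-gene counts via
#' a sparse subject-by-gene incidence product. The diagonal (each subject
#' against themself) is set to 0, mirroring heatmap display where the
#' self-comparison band is suppressed.
#'
#' @param cohort A [cohort] with at least two subjects.
#' @return A `similarity_matrix` in `raw_count` mode.
#' @export
build_similarity <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  subjects <- cohort$subjects
  if (length(subjects) < 2) stop("need at least 2 subjects", call. = FALSE)
  genes <- unique(unlist(cohort$genes_by_subject, use.names = FALSE))
  i <- rep(seq_along(subjects), lengths(cohort$genes_by_subject))
  j <- match(unlist(cohort$genes_by_subject, use.names = FALSE), genes)
  inc <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(subjects), length(genes)))
  a <- as.matrix(Matrix::tcrossprod(inc))
  diag(a) <- 0
  dimnames(a) <- list(subjects, subjects)
  new_similarity_matrix(a, "raw_count")
}

#' Log2-transform a raw similarity matrix
#'
#' Elementwise `T(n) = log2(n)` for `n >= 1` and `T(0) = 0`, so a pair
#' sharing no genes and a pair sharing one gene both map to 0 and the matrix
#' stays non-negative.
#'
#' @param m A `similarity_matrix` in `raw_count` mode.
#' @return A `similarity_matrix` in `log2` mode.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "similarity_matrix"))
  if (m$transform != "raw_count") stop("matrix is already transformed", call. = FALSE)
  v <- m$values
  v[v >= 1] <- log2(v[v >= 1])
  v[m$values < 1] <- 0
  new_similarity_matrix(v, "log2")
}

#' Cluster density factor
#'
#' The density factor (DF) of a set of subjects is the mean of all
#' off-diagonal similarity cells within the block they span — the average
#' amount of (transformed) gene sharing inside the cluster.
#'
#' @param m A `similarity_matrix`.
#' @param members Character vector of subject ids (at least 2), a subset of
#'   the matrix labels.
#' @return A single number.
#' @export
density_factor <- function(m, members) {
  stopifnot(inherits(m, "similarity_matrix"))
  if (length(members) < 2) stop("need at least 2 members", call. = FALSE)
  if (!all(members %in% m$labels)) stop("members not all in matrix labels", call. = FALSE)
  block <- m$values[members, members, drop = FALSE]
  n <- length(members)
  sum(block) / (n * (n - 1))
}

#' Write / read a similarity matrix as TSV with a JSON sidecar
#'
#' The TSV carries a `subject_id` header column and one column per subject;
#' the sidecar `<path>.json` records the transform so round-trips preserve it.
#'
#' @param m A `similarity_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly (`write_similarity`); a `similarity_matrix`
#'   (`read_similarity`).
#' @export
write_similarity <- function(m, path) {
  stopifnot(inherits(m, "similarity_matrix"))
  df <- data.frame(subject_id = m$labels, m$values, check.names = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
  jsonlite::write_json(list(transform = m$transform), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$subject_id
  side <- paste0(path, ".json")
  transform <- if (file.exists(side)) jsonlite::read_json(side)$transform else "raw_count"
  new_similarity_matrix(v, transform)
}
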