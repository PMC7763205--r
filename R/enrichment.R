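#' Gene-set over-representation analysis
#'
#' For each annotation term, a 2x2 Fisher's exact test compares the query
#' list against the background gene universe. Fold enrichment (FE) is the
#' observed number of query genes in the term divided by the number expected
#' for a random list of the same size (`expected = n_list * K_term / N_bg`).
#' Raw p-values are adjusted by the Benjamini-Hochberg step-up procedure, and
#' surviving terms are ranked by FE — an effect-size ranking, since both raw
#' and adjusted p-values grow mechanically with list size.
#'
#' @name enrichment
NULL

#' Load a term -> gene annotation
#'
#' Two formats: a two-column TSV (`term_id <TAB> gene_symbol`, optional third
#' column = term name) or GAF 2.2 (column 2 = object symbol is used as the
#' gene symbol, column 4 qualifier rows containing `NOT` are skipped, column
#' 5 = term id). Gene symbols are upper-cased; a gene annotated twice to one
#' term counts once; terms left with no genes are dropped.
#'
#' @param path Annotation file path.
#' @param format `"tsv2col"` or `"gaf"`.
#' @param background Optional character vector: the gene universe. Defaults
#'   to the union of all annotated genes. Annotated genes outside a supplied
#'   background are kept in the background (the universe must contain every
#'   annotated gene).
#' @return An object of class `annotation_set`: list with `terms` (named list
#'   term_id -> gene vector), `term_names` (named character, possibly empty)
#'   and `background`.
#' @export
load_annotation <- function(path, format = c("tsv2col", "gaf"), background = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv2col") {
    df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                            colClasses = "character")
    if (ncol(df) < 2) stop("tsv2col annotation needs at least 2 columns", call. = FALSE)
    term <- df[[1]]
    gene <- toupper(df[[2]])
    term_names <- if (ncol(df) >= 3) {
      tn <- df[[3]][!duplicated(df[[1]])]
      stats::setNames(tn, df[[1]][!duplicated(df[[1]])])
    } else character(0)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    if (length(lines) == 0) stop("empty GAF annotation", call. = FALSE)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(fields) >= 5
    fields <- fields[ok]
    qualifier <- vapply(fields, `[[`, "", 4)
    keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
    term <- vapply(fields[keep], `[[`, "", 5)
    gene <- toupper(vapply(fields[keep], `[[`, "", 3))
    term_names <- character(0)
  }
  ok <- nzchar(term) & nzchar(gene)
  term <- term[ok]; gene <- gene[ok]
  if (length(term) == 0) stop("annotation contains no usable rows", call. = FALSE)
  terms <- lapply(split(gene, term), unique)
  terms <- terms[lengths(terms) > 0]
  bg <- unique(c(toupper(background), gene))
  bg <- bg[!is.na(bg) & nzchar(bg)]
  structure(list(terms = terms, term_names = term_names, background = bg),
            class = "annotation_set")
}

#' Build an annotation set from in-memory pieces
#' @param terms Named list term_id -> character gene vector.
#' @param background Character vector; defaults to the union of annotated genes.
#' @param term_names Optional named character vector of display names.
#' @return An `annotation_set`.
#' @export
annotation_set <- function(terms, background = NULL, term_names = character(0)) {
  terms <- lapply(terms, function(g) unique(toupper(g)))
  terms <- terms[lengths(terms) > 0]
  if (length(terms) == 0) stop("no non-empty terms", call. = FALSE)
  bg <- unique(c(toupper(background), unlist(terms, use.names = FALSE)))
  structure(list(terms = terms, term_names = term_names, background = bg),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d terms over a background of %d genes\n",
              length(x$terms), length(x$background)))
  invisible(x)
}

#' Fisher over-representation test per term
#'
#' For each term the 2x2 table is
#' `[k_obs, n_list - k_obs; K_term - k_obs, N_bg - n_list - K_term + k_obs]`.
#' The default two-sided p-value follows the standard convention (the sum of
#' the probabilities of all tables no more probable than the observed one);
#' `"greater"` gives the one-sided over-representation tail. Query genes
#' outside the background are dropped (count in attribute `n_dropped`). Terms
#' with no query hit are reported with `fold_enrichment = 0`.
#'
#' @param query Character vector of gene symbols.
#' @param ann An `annotation_set`.
#' @param sidedness `"two_sided"` (default) or `"greater"`.
#' @param min_term_size Drop terms with fewer background genes than this
#'   (default 0: no floor).
#' @return Tibble with one row per tested term: `term_id`, `name`, `n_list`,
#'   `k_obs`, `K_term`, `N_bg`, `expected`, `fold_enrichment`, `p_raw`,
#'   `p_fdr` (BH across all tested terms).
#' @export
fisher_enrich <- function(query, ann, sidedness = c("two_sided", "greater"),
                          min_term_size = 0) {
  stopifnot(inherits(ann, "annotation_set"))
  sidedness <- match.arg(sidedness)
  query <- unique(toupper(query))
  in_bg <- query %in% ann$background
  n_dropped <- sum(!in_bg)
  query <- query[in_bg]
  if (length(query) == 0) stop("no query gene is in the background", call. = FALSE)
  terms <- ann$terms[lengths(ann$terms) >= min_term_size]
  n_list <- length(query)
  n_bg <- length(ann$background)
  k_obs <- vapply(terms, function(g) sum(query %in% g), integer(1))
  k_term <- lengths(terms)
  expected <- n_list * k_term / n_bg
  fe <- ifelse(k_obs == 0, 0, k_obs / expected)
  alt <- if (sidedness == "two_sided") "two.sided" else "greater"
  p_raw <- vapply(seq_along(terms), function(i) {
    tab <- matrix(c(k_obs[i], n_list - k_obs[i],
                    k_term[i] - k_obs[i], n_bg - n_list - k_term[i] + k_obs[i]),
                  nrow = 2)
    stats::fisher.test(tab, alternative = alt)$p.value
  }, numeric(1))
  p_raw <- pmin(pmax(p_raw, 0), 1)  # guard tiny floating overshoot above 1
  out <- tibble::tibble(
    term_id = names(terms),
    name = unname(ifelse(names(terms) %in% names(ann$term_names),
                         ann$term_names[names(terms)], names(terms))),
    n_list = n_list, k_obs = unname(k_obs), K_term = unname(k_term), N_bg = n_bg,
    expected = unname(expected), fold_enrichment = unname(fe),
    p_raw = unname(p_raw), p_fdr = bh_fdr(unname(p_raw))
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; the i-th output
#' corresponds to the i-th input. Adjusted values are always >= raw.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Filter and rank enrichment rows by fold enrichment
#'
#' Keeps rows with `p_fdr < fdr_max` (strict) and, when supplied,
#' `fold_enrichment >= fe_min`; rows with no query hit (`k_obs == 0`, FE
#' undefined, reported as 0) are excluded from ranking. Sorted by FE
#' descending, then `p_fdr` ascending, then `term_id`.
#'
#' @param rows Tibble from [fisher_enrich()].
#' @param fdr_max Strict FDR cutoff (default 0.005, a conservative two-tailed
#'   threshold).
#' @param fe_min Optional minimum fold enrichment (e.g. 1.5).
#' @return The filtered, ranked tibble (possibly zero rows).
#' @export
rank_and_filter <- function(rows, fdr_max = 0.005, fe_min = NULL) {
  if (nrow(rows) == 0) return(rows)
  keep <- rows$p_fdr < fdr_max & rows$k_obs > 0
  if (!is.null(fe_min)) keep <- keep & rows$fold_enrichment >= fe_min
  out <- rows[keep, , drop = FALSE]
  out[order(-out$fold_enrichment, out$p_fdr, out$term_id), , drop = FALSE]
}

#' Enrichment over several gene lists
#'
#' Runs [fisher_enrich()] + [rank_and_filter()] on each list (e.g. the seven
#' Venn partitions' gene lists). Lists with no gene in the background yield
#' an empty table rather than an error.
#'
#' @param gene_lists Named list of character vectors.
#' @param ann An `annotation_set`.
#' @param fdr_max,fe_min,sidedness Passed through.
#' @return Named list of ranked tibbles.
#' @export
enrich_pipeline <- function(gene_lists, ann, fdr_max = 0.005, fe_min = NULL,
                            sidedness = "two_sided") {
  stopifnot(is.list(gene_lists), !is.null(names(gene_lists)))
  lapply(gene_lists, function(genes) {
    genes <- unique(toupper(genes))
    if (sum(genes %in% ann$background) == 0) {
      return(tibble::tibble(term_id = character(0), name = character(0),
                            n_list = integer(0), k_obs = integer(0),
                            K_term = integer(0), N_bg = integer(0),
                            expected = numeric(0), fold_enrichment = numeric(0),
                            p_raw = numeric(0), p_fdr = numeric(0)))
    }
    rank_and_filter(fisher_enrich(genes, ann, sidedness = sidedness),
                    fdr_max = fdr_max, fe_min = fe_min)
  })
}
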