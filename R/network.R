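#' Interaction-edge enrichment of a gene set
#'
#' Given an undirected background gene-interaction network, the observed
#' number of edges among a query gene set is compared with the number
#' expected for random gene sets of the same size. The null is a seeded
#' uniform Monte-Carlo draw of same-size node samples (a degree-agnostic
#' null, unlike the degree-aware analytic null of curated PPI services);
#' the empirical one-sided p-value comes from the same draws.
#'
#' @name network
NULL

#' Read an undirected edge list
#'
#' Two-column TSV of gene symbols. Self-loops are dropped and duplicate
#' edges (in either orientation) collapse to one.
#'
#' @param path TSV path (no header by default; a header row whose first
#'   field is "gene1"/"from"/"node1" is skipped).
#' @return An object of class `interaction_graph`: list with `edges`
#'   (two-column character matrix, each row an unordered pair) and `nodes`.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("edge list needs two columns", call. = FALSE)
  if (tolower(df[1, 1]) %in% c("gene1", "from", "node1")) df <- df[-1, , drop = FALSE]
  interaction_graph(df[[1]], df[[2]])
}

#' Build an interaction graph from endpoint vectors
#' @param from,to Character vectors of gene symbols (same length).
#' @return An `interaction_graph`.
#' @export
interaction_graph <- function(from, to) {
  stopifnot(length(from) == length(to))
  from <- toupper(trimws(from)); to <- toupper(trimws(to))
  keep <- from != to & nzchar(from) & nzchar(to)
  a <- pmin(from[keep], to[keep]); b <- pmax(from[keep], to[keep])
  dup <- duplicated(paste(a, b, sep = "\r"))
  edges <- cbind(a[!dup], b[!dup])
  structure(list(edges = edges, nodes = sort(unique(c(edges)))),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

count_edges_within <- function(graph, genes) {
  sum(graph$edges[, 1] %in% genes & graph$edges[, 2] %in% genes)
}

#' Genes carried by many subjects
#'
#' @param cohort A [cohort].
#' @param members Subject ids to consider (default: all subjects).
#' @param min_patients Minimum number of distinct carriers (>= 1).
#' @return Character vector of gene symbols.
#' @export
frequent_genes <- function(cohort, members = NULL, min_patients = 50) {
  stopifnot(inherits(cohort, "cohort"))
  if (min_patients < 1) stop("'min_patients' must be >= 1", call. = FALSE)
  if (is.null(members)) members <- cohort$subjects
  ev <- cohort$events[cohort$events$subject_id %in% members, , drop = FALSE]
  carriers <- tapply(ev$subject_id, ev$gene_symbol, function(s) length(unique(s)))
  sort(names(carriers)[carriers >= min_patients])
}

#' Ratio of observed to expected interaction edges
#'
#' Compares the arithmetic: `ratio = observed / expected`, flagging the
#' degenerate `expected = 0` case. Used both on Monte-Carlo expectations and
#' on externally reported edge counts.
#'
#' @param observed,expected Edge counts (expected may be fractional).
#' @return List with `observed`, `expected`, `ratio`, `infinite_ratio` flag.
#' @export
edge_ratio_stats <- function(observed, expected) {
  inf <- expected == 0
  list(observed = observed, expected = expected,
       ratio = if (inf) Inf else observed / expected,
       infinite_ratio = inf)
}

#' Observed vs expected edges for a gene set
#'
#' `observed` counts network edges with both endpoints in the query set;
#' `expected` is the mean observed count over `n_random` uniform same-size
#' node samples drawn with the given seed. Query genes absent from the
#' network are dropped first (count in `n_dropped`).
#'
#' @param genes Character vector of query gene symbols.
#' @param graph An `interaction_graph`.
#' @param n_random Number of Monte-Carlo samples (>= 100).
#' @param seed Integer seed; the same seed reproduces the result exactly.
#' @return List with `observed`, `expected`, `ratio`, `p_empirical` (one-sided,
#'   add-one corrected), `n_genes`, `n_dropped`, `n_random`, `seed`,
#'   `infinite_ratio`.
#' @export
edge_ratio <- function(genes, graph, n_random = 1000, seed = 1) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (n_random < 100) stop("'n_random' must be >= 100", call. = FALSE)
  genes <- unique(toupper(genes))
  in_graph <- genes %in% graph$nodes
  n_dropped <- sum(!in_graph)
  genes <- genes[in_graph]
  observed <- count_edges_within(graph, genes)
  n <- length(genes)
  if (n < 2) {
    return(c(edge_ratio_stats(observed, 0),
             list(p_empirical = NA_real_, n_genes = n, n_dropped = n_dropped,
                  n_random = n_random, seed = seed)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_random), function(i) {
    count_edges_within(graph, sample(graph$nodes, n))
  }, numeric(1))
  expected <- mean(null_counts)
  stats <- edge_ratio_stats(observed, expected)
  stats$p_empirical <- (1 + sum(null_counts >= observed)) / (n_random + 1)
  c(stats, list(n_genes = n, n_dropped = n_dropped, n_random = n_random, seed = seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
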