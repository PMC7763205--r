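#' Synthetic variant cohorts with planted structure
#'
#' Generates VariCarta-style event tables in which cluster structure, term
#' enrichment and network density are planted and therefore known: each
#' planted cluster draws most of its variants from a private gene module, all
#' clustered subjects sample a common "shared core" pool at a low rate (so
#' the three-way intersection of shared-variant sets is populated), and mixed
#' subjects draw from background genes only, sharing essentially nothing.
#' Every gene carries a small fixed number of possible variant sites, so the
#' same variant recurs across subjects and sharedness is well-defined at the
#' variant level. Event-table nuisance structure — duplicate events re-emitted
#' under a second source publication, a small fraction of targeted-sequencing
#' records, rare inherited variants, sparse ExAC/CADD annotation — is planted
#' at configurable rates matching a literature-aggregated de novo cohort.
#'
#' @name synthetic
NULL

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a small cohort (3 planted clusters of 30 subjects plus
#' 10 mixed, ~70 variants per subject, 60% drawn from the subject's module
#' pool and 12% from the shared core) whose planted structure is strong
#' enough that the full pipeline should recover it.
#'
#' @param n_clusters Number of planted dense clusters.
#' @param cluster_sizes Integer vector (length `n_clusters`) of subjects per cluster.
#' @param n_mixed Subjects drawing from background only.
#' @param module_pool_size Genes in each cluster's private module pool.
#' @param shared_pool_size Genes in the shared core pool sampled by all
#'   clustered subjects.
#' @param background_pool_size Genes in the background pool.
#' @param variants_per_subject Poisson mean of per-subject variant count.
#' @param p_module Probability a clustered subject's variant comes from its
#'   module pool.
#' @param p_shared Probability it comes from the shared core
#'   (`p_module + p_shared <= 1`; the rest is background).
#' @param sites_per_gene Distinct variant sites per gene.
#' @param duplicate_event_rate Fraction of events re-emitted under a second
#'   source publication.
#' @param targeted_rate Fraction of records labeled targeted sequencing.
#' @param inherited_rate Fraction of inherited (vs de novo) variants.
#' @param exac_annotated_rate,cadd_annotated_rate Fractions of events
#'   carrying an ExAC / CADD score.
#' @param planted_terms_per_module,module_term_size Terms planted over each
#'   module pool and their size.
#' @param shared_terms,shared_term_size Terms planted over the shared core.
#' @param n_noise_terms,noise_term_size Terms over random universe genes.
#' @param n_sources Number of synthetic source publications.
#' @param edge_within_rate Edge probability within each module/shared pool.
#' @param n_background_edges Random background edges.
#' @param seed Integer seed (mandatory; all randomness flows from it).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_clusters = 3,
                             cluster_sizes = rep(30L, n_clusters),
                             n_mixed = 10,
                             module_pool_size = 250,
                             shared_pool_size = 50,
                             background_pool_size = 20000,
                             variants_per_subject = 70,
                             p_module = 0.6,
                             p_shared = 0.12,
                             sites_per_gene = 2,
                             duplicate_event_rate = 0.1,
                             targeted_rate = 0.02,
                             inherited_rate = 0.003,
                             exac_annotated_rate = 0.009,
                             cadd_annotated_rate = 0.013,
                             planted_terms_per_module = 5,
                             module_term_size = 40,
                             shared_terms = 5,
                             shared_term_size = 10,
                             n_noise_terms = 50,
                             noise_term_size = 15,
                             n_sources = 10,
                             edge_within_rate = 0.05,
                             n_background_edges = 2000,
                             seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  probs <- c(p_module, p_shared, duplicate_event_rate, targeted_rate,
             inherited_rate, exac_annotated_rate, cadd_annotated_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  if (p_module + p_shared > 1) stop("p_module + p_shared must be <= 1", call. = FALSE)
  if (length(cluster_sizes) != n_clusters) {
    stop("'cluster_sizes' must have length n_clusters", call. = FALSE)
  }
  sizes <- c(cluster_sizes, module_pool_size, shared_pool_size,
             background_pool_size, variants_per_subject, sites_per_gene)
  if (any(sizes <= 0)) stop("sizes must be positive", call. = FALSE)
  if (module_term_size > module_pool_size) {
    stop("module terms larger than the module pool are infeasible", call. = FALSE)
  }
  if (shared_term_size > shared_pool_size) {
    stop("shared-core terms larger than the shared pool are infeasible", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

seq_pad <- function(prefix, n) sprintf("%s%0*d", prefix, max(4, nchar(n)), seq_len(n))

#' Generate a synthetic cohort
#'
#' All randomness is driven by `cfg$seed`; the same configuration generates
#' identical output every time (the caller's RNG state is left untouched).
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `synthetic_cohort`: `events` (tibble in the
#'   normalized event layout of [read_events()]), `annotation` (an
#'   `annotation_set` whose background is the full gene universe), `graph`
#'   (an `interaction_graph`), `truth` (subject labels, planted pools,
#'   planted/noise term ids, seed) and `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  module_pools <- lapply(seq_len(cfg$n_clusters), function(m) {
    seq_pad(sprintf("M%dG", m), cfg$module_pool_size)
  })
  names(module_pools) <- sprintf("M%d", seq_len(cfg$n_clusters))
  shared_pool <- seq_pad("SCG", cfg$shared_pool_size)
  background_pool <- seq_pad("BGG", cfg$background_pool_size)
  universe <- c(unlist(module_pools, use.names = FALSE), shared_pool, background_pool)

  n_subjects <- sum(cfg$cluster_sizes) + cfg$n_mixed
  subjects <- seq_pad("S", n_subjects)
  truth_class <- c(rep(names(module_pools), cfg$cluster_sizes),
                   rep("mixed", cfg$n_mixed))
  names(truth_class) <- subjects
  subject_source <- sample(seq_pad("study_", cfg$n_sources), n_subjects, replace = TRUE)

  # fixed per-site variant identity so the same draw recurs across subjects
  gene_index <- stats::setNames(seq_along(universe), universe)
  refs <- c("A", "C", "G", "T")
  site_ref <- function(g, s) refs[(gene_index[g] + s) %% 4 + 1]
  site_alt <- function(g, s) refs[(gene_index[g] + s + 1) %% 4 + 1]
  categories <- c("nonsynonymous SNV", "synonymous SNV", "frameshift insertion",
                  "frameshift deletion", "stopgain")

  draw_subject <- function(i) {
    n <- stats::rpois(1, cfg$variants_per_subject)
    if (n == 0) n <- 1
    cls <- truth_class[i]
    if (cls == "mixed") {
      genes <- sample(background_pool, n, replace = TRUE)
    } else {
      src <- sample(c("module", "shared", "background"), n, replace = TRUE,
                    prob = c(cfg$p_module, cfg$p_shared, 1 - cfg$p_module - cfg$p_shared))
      genes <- character(n)
      genes[src == "module"] <- sample(module_pools[[cls]], sum(src == "module"), replace = TRUE)
      genes[src == "shared"] <- sample(shared_pool, sum(src == "shared"), replace = TRUE)
      genes[src == "background"] <- sample(background_pool, sum(src == "background"), replace = TRUE)
    }
    sites <- sample.int(cfg$sites_per_gene, n, replace = TRUE)
    tibble::tibble(subject_id = subjects[i], gene_symbol = genes, site = sites)
  }
  base <- dplyr::bind_rows(lapply(seq_len(n_subjects), draw_subject))

  g_idx <- gene_index[base$gene_symbol]
  events <- tibble::tibble(
    subject_id = base$subject_id,
    gene_symbol = base$gene_symbol,
    chrom = as.character((g_idx %% 22) + 1),
    pos = as.numeric(g_idx * 1000 + base$site),
    ref = refs[(g_idx + base$site) %% 4 + 1],
    alt = refs[(g_idx + base$site + 1) %% 4 + 1],
    variant_category = categories[(g_idx + base$site) %% length(categories) + 1],
    sequencing_type = ifelse(stats::runif(nrow(base)) < cfg$targeted_rate,
                             "targeted", "whole_genome"),
    inheritance = ifelse(stats::runif(nrow(base)) < cfg$inherited_rate,
                         "inherited", "de_novo"),
    exac_af = NA_real_,
    cadd_score = NA_real_,
    source_ref = subject_source[match(base$subject_id, subjects)],
    event_label = NA_character_
  )
  # sparse score annotation; ExAC mixture matches the reported tail fractions
  # (2.5% of scored variants above 0.01, 0.7% above 0.05)
  has_exac <- stats::runif(nrow(events)) < cfg$exac_annotated_rate
  n_ex <- sum(has_exac)
  if (n_ex > 0) {
    band <- sample(c("rare", "low", "common"), n_ex, replace = TRUE,
                   prob = c(0.975, 0.018, 0.007))
    af <- numeric(n_ex)
    af[band == "rare"] <- stats::runif(sum(band == "rare"), 0, 0.01)
    af[band == "low"] <- stats::runif(sum(band == "low"), 0.01, 0.05)
    af[band == "common"] <- stats::runif(sum(band == "common"), 0.05, 0.2)
    events$exac_af[has_exac] <- af
  }
  has_cadd <- stats::runif(nrow(events)) < cfg$cadd_annotated_rate
  events$cadd_score[has_cadd] <- pmin(stats::rgamma(sum(has_cadd), shape = 2, scale = 8), 60)

  # duplicate events: re-emitted under a second source publication
  n_dup <- round(cfg$duplicate_event_rate * nrow(events))
  if (n_dup > 0) {
    dup <- events[sample.int(nrow(events), n_dup), , drop = FALSE]
    dup$source_ref <- paste0(dup$source_ref, "_reanalysis")
    events <- dplyr::bind_rows(events, dup)
  }
  events <- events[sample.int(nrow(events)), , drop = FALSE]  # shuffle row order

  # planted annotation: module terms, shared-core terms, noise terms
  terms <- list()
  module_terms <- list()
  for (m in names(module_pools)) {
    ids <- sprintf("T%s_%02d", m, seq_len(cfg$planted_terms_per_module))
    for (id in ids) terms[[id]] <- sample(module_pools[[m]], cfg$module_term_size)
    module_terms[[m]] <- ids
  }
  shared_ids <- sprintf("TSHARED_%02d", seq_len(cfg$shared_terms))
  for (id in shared_ids) terms[[id]] <- sample(shared_pool, cfg$shared_term_size)
  noise_ids <- sprintf("TNOISE_%03d", seq_len(cfg$n_noise_terms))
  for (id in noise_ids) terms[[id]] <- sample(universe, cfg$noise_term_size)
  ann <- annotation_set(terms, background = universe)

  # interaction network: dense within planted pools, sparse background
  pool_edges <- function(pool) {
    pairs <- utils::combn(pool, 2)
    keep <- stats::runif(ncol(pairs)) < cfg$edge_within_rate
    t(pairs[, keep, drop = FALSE])
  }
  within <- do.call(rbind, lapply(c(module_pools, list(shared = shared_pool)), pool_edges))
  bg_from <- sample(universe, cfg$n_background_edges, replace = TRUE)
  bg_to <- sample(universe, cfg$n_background_edges, replace = TRUE)
  graph <- interaction_graph(c(within[, 1], bg_from), c(within[, 2], bg_to))

  structure(
    list(events = events,
         annotation = ann,
         graph = graph,
         truth = list(labels = truth_class,
                      module_pools = module_pools,
                      shared_pool = shared_pool,
                      module_terms = module_terms,
                      shared_terms = shared_ids,
                      noise_terms = noise_ids,
                      seed = cfg$seed),
         config = cfg),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d events, %d subjects (%s + %d mixed), seed %d\n",
              nrow(x$events), length(x$truth$labels),
              paste(x$config$cluster_sizes, collapse = "+"), x$config$n_mixed,
              x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits `events.csv` (VariCarta-style column names, the exact dialect
#' [read_events()] reads by default), `annotation.tsv` (term, gene),
#' `edges.tsv` and `truth.json` under `dir`.
#'
#' @param sim A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- sim$events
  seq_out <- c(whole_genome = "whole genome sequencing",
               exome = "exome sequencing",
               targeted = "targeted sequencing")
  inh_out <- c(de_novo = "de novo", inherited = "inherited", unknown = "")
  out <- data.frame(
    `Subject id` = ev$subject_id,
    `Gene Symbol` = ev$gene_symbol,
    Chromosome = ev$chrom,
    Position = format(ev$pos, scientific = FALSE, trim = TRUE),
    Ref = ev$ref,
    Alt = ev$alt,
    `Variant Category` = ev$variant_category,
    `Sequencing Type` = unname(seq_out[ev$sequencing_type]),
    Inheritance = unname(inh_out[ev$inheritance]),
    `ExAC Frequency` = ifelse(is.na(ev$exac_af), "", format(ev$exac_af, digits = 6)),
    `CADD Score` = ifelse(is.na(ev$cadd_score), "", format(ev$cadd_score, digits = 6)),
    Reference = ev$source_ref,
    check.names = FALSE
  )
  readr::write_csv(out, file.path(dir, "events.csv"), progress = FALSE)
  ann_rows <- data.frame(
    term = rep(names(sim$annotation$terms), lengths(sim$annotation$terms)),
    gene = unlist(sim$annotation$terms, use.names = FALSE)
  )
  readr::write_tsv(ann_rows, file.path(dir, "annotation.tsv"),
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(as.data.frame(sim$graph$edges), file.path(dir, "edges.tsv"),
                   col_names = FALSE, progress = FALSE)
  truth_out <- sim$truth
  truth_out$labels <- as.list(truth_out$labels)  # keep subject ids as JSON keys
  jsonlite::write_json(truth_out, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Compare recovered clusters with planted truth
#'
#' @param truth Named character vector subject id -> planted class (the mixed
#'   group counts as its own class), or a `synthetic_cohort` / its `truth`
#'   list.
#' @param model A `cluster_model` (or a named assignment vector).
#' @return List with `ari` (adjusted Rand index) and `purity` (named vector:
#'   per recovered cluster, the share of its dominant planted class).
#' @export
evaluate_recovery <- function(truth, model) {
  if (inherits(truth, "synthetic_cohort")) truth <- truth$truth
  if (is.list(truth) && !is.null(truth$labels)) truth <- unlist(truth$labels)
  assignment <- if (inherits(model, "cluster_model")) model$assignment else model
  if (is.null(names(truth)) || is.null(names(assignment))) {
    stop("both partitions must be named by subject id", call. = FALSE)
  }
  if (!setequal(names(truth), names(assignment))) {
    stop("subject universes differ between truth and model", call. = FALSE)
  }
  truth <- truth[names(assignment)]
  ari <- mclust::adjustedRandIndex(truth, assignment)
  purity <- vapply(split(truth, assignment),
                   function(t) max(table(t)) / length(t), numeric(1))
  list(ari = ari, purity = purity)
}
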