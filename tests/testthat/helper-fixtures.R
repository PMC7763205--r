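# In-code fixtures: tiny event tables and cohorts built programmatically.

# A minimal event tibble in the normalized layout (coordinates absent, so the
# variant key falls back to gene|category; one variant per gene).
events_from_genes <- function(genes_by_subject, source_ref = "study_1",
                              sequencing_type = "whole_genome") {
  rows <- lapply(names(genes_by_subject), function(s) {
    g <- genes_by_subject[[s]]
    tibble::tibble(
      subject_id = s, gene_symbol = toupper(g),
      chrom = NA_character_, pos = NA_real_, ref = NA_character_, alt = NA_character_,
      variant_category = "nonsynonymous SNV",
      sequencing_type = sequencing_type,
      inheritance = "de_novo",
      exac_af = NA_real_, cadd_score = NA_real_,
      source_ref = source_ref, event_label = NA_character_
    )
  })
  dplyr::bind_rows(rows)
}

cohort_from_genes <- function(genes_by_subject, ...) {
  dedup_events(events_from_genes(genes_by_subject, ...))
}

# Write a small VariCarta-dialect CSV and return its path.
write_event_csv <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "events.csv")
  writeLines(lines, path)
  path
}

varicarta_header <- paste("Subject id", "Gene Symbol", "Chromosome", "Position",
                          "Ref", "Alt", "Variant Category", "Sequencing Type",
                          "Inheritance", "ExAC Frequency", "CADD Score",
                          "Reference", sep = ",")

# A symmetric similarity matrix object from a plain matrix.
sim_from_matrix <- function(v, transform = "log2", labels = NULL) {
  if (is.null(labels)) labels <- paste0("S", seq_len(nrow(v)))
  dimnames(v) <- list(labels, labels)
  patsim:::new_similarity_matrix(v, transform)
}

# Random symmetric distance matrix with zero diagonal (continuous entries,
# ties have probability zero).
random_dist_matrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0.1, 10)
  d <- d + t(d)
  dimnames(d) <- list(paste0("S", 1:n), paste0("S", 1:n))
  d
}
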