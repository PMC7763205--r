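#' Variant event tables: reading, validation, deduplication, filtering
#'
#' @description
#' Functions to turn a VariCarta-style CSV of variant events (one row per
#' subject x variant observation) into a deduplicated [cohort] with per-subject
#' variant and gene sets, and to apply the standard pre-analysis filters
#' (sequencing type, ExAC allele frequency, CADD deleteriousness bins).
#'
#' @name variant_io
NULL

#' Allowed sequencing types
#' @keywords internal
SEQ_TYPES <- c("whole_genome", "exome", "targeted")

#' Allowed inheritance statuses
#' @keywords internal
INHERITANCE_TYPES <- c("de_novo", "inherited", "unknown")

#' Default column-name map for VariCarta-style CSVs
#'
#' A dialect maps event-table roles to the column names of a concrete CSV.
#' Required roles: `subject_id`, `gene_symbol`, `sequencing_type`. Optional
#' roles (`chrom`, `pos`, `ref`, `alt`, `variant_category`, `inheritance`,
#' `exac_af`, `cadd_score`, `source_ref`, `event_label`) are used when the
#' column is present and ignored otherwise.
#'
#' @return Named character vector, role -> column name.
#' @export
#' @examples
#' varicarta_dialect()
varicarta_dialect <- function() {
  c(
    subject_id       = "Subject id",
    gene_symbol      = "Gene Symbol",
    chrom            = "Chromosome",
    pos              = "Position",
    ref              = "Ref",
    alt              = "Alt",
    variant_category = "Variant Category",
    sequencing_type  = "Sequencing Type",
    inheritance      = "Inheritance",
    exac_af          = "ExAC Frequency",
    cadd_score       = "CADD Score",
    source_ref       = "Reference",
    event_label      = "Event Label"
  )
}

#' Normalize free-text sequencing-type strings
#'
#' Maps strings such as "whole genome sequencing", "exome sequencing" or
#' "targeted analysis sequencing" onto the canonical set
#' `c("whole_genome", "exome", "targeted")`.
#'
#' @param x Character vector.
#' @return Character vector over the canonical set (NA when unrecognized).
#' @export
normalize_sequencing_type <- function(x) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x0))
  out[grepl("genome", x0)] <- "whole_genome"
  out[grepl("exome", x0)] <- "exome"
  out[grepl("target", x0)] <- "targeted"
  out[x0 %in% SEQ_TYPES] <- x0[x0 %in% SEQ_TYPES]
  out
}

norm_inheritance <- function(x) {
  x0 <- tolower(gsub("[ -]", "_", trimws(as.character(x))))
  out <- rep("unknown", length(x0))
  out[grepl("de_novo|denovo", x0)] <- "de_novo"
  out[grepl("inherit|maternal|paternal", x0)] <- "inherited"
  out[is.na(x) | x0 == ""] <- "unknown"
  out
}

num_or_na <- function(x, what, warn = TRUE) {
  x0 <- trimws(as.character(x))
  x0[x0 == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x0))
  bad <- !is.na(x0) & is.na(out)
  if (warn && any(bad)) {
    warning(sprintf("%d unparseable %s value(s) set to missing", sum(bad), what),
            call. = FALSE)
  }
  out
}

#' Read a variant event table
#'
#' Parses a comma-separated, UTF-8, headered event table into one row per
#' variant event. Rows missing the subject id or the gene symbol are rejected
#' (their count is recorded in the `n_rejected` attribute). Unparseable
#' position / ExAC / CADD cells become missing values with a warning; row
#' order is preserved.
#'
#' @param path Path to the CSV file.
#' @param dialect Named character vector mapping roles to column names; see
#'   [varicarta_dialect()]. Roles whose columns are absent from the file are
#'   filled with missing values, except the required roles `subject_id`,
#'   `gene_symbol` and `sequencing_type`, which must resolve.
#' @return A tibble of events with columns `subject_id`, `gene_symbol`,
#'   `chrom`, `pos`, `ref`, `alt`, `variant_category`, `sequencing_type`,
#'   `inheritance`, `exac_af`, `cadd_score`, `source_ref`, `event_label`,
#'   plus attribute `n_rejected`.
#' @export
read_events <- function(path, dialect = varicarta_dialect()) {
  stopifnot(is.character(path), length(path) == 1)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  for (role in c("subject_id", "gene_symbol", "sequencing_type")) {
    col <- dialect[[role]]
    if (is.null(col) || !col %in% names(raw)) {
      stop(sprintf("required column for role '%s' (%s) not found in %s",
                   role, if (is.null(col)) "<unmapped>" else col, path),
           call. = FALSE)
    }
  }
  pull <- function(role) {
    col <- dialect[[role]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  events <- tibble::tibble(
    subject_id       = trimws(pull("subject_id")),
    gene_symbol      = toupper(trimws(pull("gene_symbol"))),
    chrom            = trimws(pull("chrom")),
    pos              = num_or_na(pull("pos"), "position"),
    ref              = trimws(pull("ref")),
    alt              = trimws(pull("alt")),
    variant_category = trimws(pull("variant_category")),
    sequencing_type  = normalize_sequencing_type(pull("sequencing_type")),
    inheritance      = norm_inheritance(pull("inheritance")),
    exac_af          = num_or_na(pull("exac_af"), "ExAC frequency"),
    cadd_score       = num_or_na(pull("cadd_score"), "CADD score"),
    source_ref       = trimws(pull("source_ref")),
    event_label      = trimws(pull("event_label"))
  )
  bad_af <- !is.na(events$exac_af) & (events$exac_af < 0 | events$exac_af > 1)
  if (any(bad_af)) {
    warning(sprintf("%d ExAC value(s) outside [0,1] set to missing", sum(bad_af)),
            call. = FALSE)
    events$exac_af[bad_af] <- NA_real_
  }
  keep <- !is.na(events$subject_id) & events$subject_id != "" &
    !is.na(events$gene_symbol) & events$gene_symbol != ""
  n_rejected <- sum(!keep)
  if (n_rejected > 0) {
    message(sprintf("read_events: rejected %d row(s) with missing subject or gene", n_rejected))
  }
  events <- events[keep, , drop = FALSE]
  attr(events, "n_rejected") <- n_rejected
  events
}

#' Canonical variant identity keys
#'
#' The deduplication key prefers coordinate identity `chrom:pos:ref:alt` when
#' all four fields are present, and falls back to
#' `gene|variant category|event label` otherwise, so that the same change in
#' the same subject reported by two publications collapses to one variant.
#'
#' @param events Event tibble from [read_events()].
#' @return Character vector of keys, one per event row.
#' @export
variant_key <- function(events) {
  has_coord <- !is.na(events$chrom) & events$chrom != "" &
    !is.na(events$pos) & !is.na(events$ref) & events$ref != "" &
    !is.na(events$alt) & events$alt != ""
  key <- character(nrow(events))
  key[has_coord] <- paste(events$chrom[has_coord],
                          format(events$pos[has_coord], scientific = FALSE, trim = TRUE),
                          events$ref[has_coord], events$alt[has_coord], sep = ":")
  fb <- !has_coord
  lab <- events$event_label[fb]
  lab[is.na(lab)] <- ""
  key[fb] <- paste(events$gene_symbol[fb], events$variant_category[fb], lab, sep = "|")
  key
}

#' Deduplicate events into a cohort
#'
#' Collapses events to unique (subject, variant key) pairs — a variant event
#' reported by several source publications for the same subject counts once —
#' and derives per-subject variant-key sets and gene sets.
#'
#' @param events Event tibble from [read_events()].
#' @return An object of class `cohort`: a list with `subjects` (ordered ids),
#'   `variants_by_subject`, `genes_by_subject` (named lists of character
#'   sets), `events` (the deduplicated event tibble with a `variant_key`
#'   column), and `stats` (total events, unique variants, duplicates removed).
#' @export
dedup_events <- function(events) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0) {
    return(new_cohort(character(), list(), list(),
                      events = tibble::tibble(), n_total = 0L, n_unique = 0L))
  }
  key <- variant_key(events)
  pair <- paste(events$subject_id, key, sep = "\r")
  first <- !duplicated(pair)
  dedup <- events[first, , drop = FALSE]
  dedup$variant_key <- key[first]
  subjects <- unique(dedup$subject_id)
  variants_by_subject <- split(dedup$variant_key, factor(dedup$subject_id, levels = subjects))
  genes_by_subject <- lapply(
    split(dedup$gene_symbol, factor(dedup$subject_id, levels = subjects)), unique)
  variants_by_subject <- lapply(variants_by_subject, unique)
  new_cohort(subjects, variants_by_subject, genes_by_subject,
             events = dedup, n_total = nrow(events), n_unique = nrow(dedup))
}

new_cohort <- function(subjects, variants_by_subject, genes_by_subject, events,
                       n_total, n_unique) {
  structure(
    list(
      subjects = subjects,
      variants_by_subject = variants_by_subject,
      genes_by_subject = genes_by_subject,
      events = events,
      stats = list(total_events = n_total,
                   unique_variants = n_unique,
                   duplicates_removed = n_total - n_unique)
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d unique subject-variant pairs (%d duplicate events removed)\n",
              length(x$subjects), x$stats$unique_variants, x$stats$duplicates_removed))
  invisible(x)
}

#' Keep events with an allowed sequencing type
#'
#' @param events Event tibble.
#' @param keep Non-empty subset of `c("whole_genome", "exome", "targeted")`.
#' @return Filtered event tibble with attribute `n_removed`.
#' @export
filter_by_sequencing <- function(events, keep = c("whole_genome", "exome")) {
  if (length(keep) == 0) stop("'keep' must be non-empty", call. = FALSE)
  if (!all(keep %in% SEQ_TYPES)) {
    stop("unknown sequencing type(s): ", paste(setdiff(keep, SEQ_TYPES), collapse = ", "),
         call. = FALSE)
  }
  sel <- events$sequencing_type %in% keep
  out <- events[sel, , drop = FALSE]
  attr(out, "n_removed") <- sum(!sel)
  out
}

#' Filter events by ExAC allele frequency
#'
#' Keeps events whose population allele frequency is strictly below `max_af`.
#' When `require_score = TRUE` (default) events without a reported frequency
#' are dropped, so the surviving set contains only scored rare variants.
#'
#' @param events Event tibble.
#' @param max_af Maximum allele frequency, in (0, 1]; the bound is strict.
#' @param require_score Drop events lacking a score? Default `TRUE`.
#' @return Filtered event tibble with attribute `n_removed`.
#' @export
filter_by_exac <- function(events, max_af, require_score = TRUE) {
  if (!is.numeric(max_af) || length(max_af) != 1 || max_af <= 0 || max_af > 1) {
    stop("'max_af' must be a single value in (0, 1]", call. = FALSE)
  }
  scored <- !is.na(events$exac_af)
  sel <- (scored & events$exac_af < max_af) | (!require_score & !scored)
  out <- events[sel, , drop = FALSE]
  attr(out, "n_removed") <- sum(!sel)
  out
}

cadd_bin_labels <- function(edges) {
  whole <- all(edges == floor(edges))
  first <- sprintf("<%s", format(edges[1], trim = TRUE))
  last <- sprintf(">=%s", format(edges[length(edges)], trim = TRUE))
  mid <- character(0)
  if (length(edges) > 1) {
    lo <- edges[-length(edges)]
    hi <- edges[-1]
    mid <- if (whole) {
      sprintf("%d-%d", as.integer(lo), as.integer(hi) - 1L)
    } else {
      sprintf("[%s,%s)", format(lo, trim = TRUE), format(hi, trim = TRUE))
    }
  }
  c(first, mid, last)
}

#' Bin events by CADD deleteriousness score
#'
#' Bins are left-closed, right-open — with edges `c(10, 20, 30, 40)` the bins
#' are `<10`, `10-19`, `20-29`, `30-39`, `>=40` — and events without a CADD
#' score land in an extra `unscored` bucket, so that every event lands in
#' exactly one bin.
#'
#' @param events Event tibble.
#' @param edges Strictly increasing numeric bin boundaries.
#' @return Named list of event tibbles, one per bin label plus `unscored`.
#' @export
bin_by_cadd <- function(events, edges = c(10, 20, 30, 40)) {
  if (length(edges) < 1 || is.unsorted(edges, strictly = TRUE)) {
    stop("'edges' must be strictly increasing", call. = FALSE)
  }
  labels <- cadd_bin_labels(edges)
  scored <- !is.na(events$cadd_score)
  idx <- findInterval(events$cadd_score[scored], edges) + 1L  # 1 = below first edge
  bins <- stats::setNames(
    lapply(seq_along(labels), function(i) events[scored, , drop = FALSE][idx == i, , drop = FALSE]),
    labels
  )
  bins$unscored <- events[!scored, , drop = FALSE]
  bins
}
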