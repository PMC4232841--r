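# Variant database construction: apply each event to its template
# transcript, translate the largest ORF of the variant mRNA, keep only
# products that differ from the template's annotated protein, de-duplicate,
# tag, and merge with a reference proteome whose headers are preserved
# verbatim.

#' Predict the protein product of a splicing event
#'
#' Composes the splice engine (event application), the ORF engine (largest
#' ATG-initiated ORF) and translation. Products identical to the template's
#' annotated protein are discarded — only variants altering the amino-acid
#' composition are of interest — as are events whose variant mRNA encodes no
#' qualifying ORF.
#'
#' @param t a [transcript()] with an annotated CDS.
#' @param e a [splice_event()] or [combined_event()].
#' @param config an [sp_config()].
#' @return an object of class `variant_protein`, or `NULL` (no ORF, or
#'   product identical to the reference protein). The object carries the
#'   variant protein `sequence`, the `tag` ([header_tag()]), the ORF start
#'   (`tis_mrna_offset`), the variant mRNA, the template's
#'   `reference_protein` and CDS start, and the splice bookkeeping
#'   (`modified_regions`, `coord_map`).
#' @export
predict_variant_protein <- function(t, e, config = sp_config()) {
  predict_variant_detail(t, e, config)$protein
}

# As predict_variant_protein, but also reports why no product was kept:
# one of "kept", "no_orf", "identical".
predict_variant_detail <- function(t, e, config = sp_config()) {
  stopifnot(inherits(t, "transcript"))
  if (is.na(t$cds_start)) {
    stop("transcript ", t$transcript_id, " has no annotated CDS")
  }
  vt <- apply_event(t, e)
  orf <- largest_orf(vt$sequence, allow_open_ended = config$allow_open_ended)
  if (is.null(orf)) return(list(protein = NULL, reason = "no_orf"))
  prot <- translate_orf(vt$sequence, orf)
  if (!nzchar(prot)) return(list(protein = NULL, reason = "no_orf"))
  ref_prot <- reference_protein(t)
  if (identical(prot, ref_prot)) {
    return(list(protein = NULL, reason = "identical"))
  }
  vp <- structure(list(
    sequence = prot,
    tag = header_tag(t$transcript_id, event_code(e, config), e$event_id),
    tis_mrna_offset = orf$start,
    orf_end = orf$end,
    variant_mrna = vt$sequence,
    reference_protein = ref_prot,
    ref_cds_start = t$cds_start,
    ref_cds_end = t$cds_end,
    event_ref = e$event_id,
    source_transcript_id = t$transcript_id,
    modified_regions = vt$modified_regions,
    coord_map = vt$coord_map,
    ref_length = vt$ref_length
  ), class = "variant_protein")
  list(protein = vp, reason = "kept")
}

#' @export
print.variant_protein <- function(x, ...) {
  cat("<variant_protein>", encode_header(x$tag),
      sprintf("(%d aa, TIS at mRNA offset %d)\n", nchar(x$sequence),
              x$tis_mrna_offset))
  invisible(x)
}

#' Build the merged search database
#'
#' Filters events by support, predicts variant proteins, drops events with
#' no qualifying or no altered product, de-duplicates exact duplicate
#' variant sequences (the lexicographically first event id is kept; merged
#' ids are recorded), and emits tagged variant records followed by the
#' reference proteome verbatim. Output ordering is fixed (variants by event
#' id, then reference records in input order) so identical inputs yield
#' byte-identical FASTA.
#'
#' @param transcripts list of [transcript()] objects (or a single one).
#' @param events list of [splice_event()] / [combined_event()] objects.
#' @param reference_proteome named character vector or `AAStringSet`;
#'   names/descriptions are preserved verbatim.
#' @param config an [sp_config()]; `min_support` applies here.
#' @return an object of class `variant_db` with `variants` (list of
#'   `variant_protein`), `headers`/`sequences` (the full record set in
#'   output order), `reference` (the proteome), and `report` (a data frame
#'   of per-stage counts; `duplicates` maps merged event ids).
#' @export
build_database <- function(transcripts, events, reference_proteome = NULL,
                           config = sp_config()) {
  if (inherits(transcripts, "transcript")) transcripts <- list(transcripts)
  names(transcripts) <- vapply(transcripts, `[[`, character(1),
                               "transcript_id")
  ids <- vapply(events, `[[`, character(1), "event_id")
  if (anyDuplicated(ids)) {
    stop("duplicate event ids: ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "))
  }
  tids <- vapply(events, `[[`, character(1), "transcript_id")
  unknown <- setdiff(tids, names(transcripts))
  if (length(unknown)) {
    stop("events reference unknown transcripts: ",
         paste(unknown, collapse = ", "))
  }
  reference <- if (is.null(reference_proteome)) {
    structure(character(0), names = character(0))
  } else as_protein_vector(reference_proteome)

  n_events <- length(events)
  support <- vapply(events, function(e) as.integer(e$support_count),
                    integer(1))
  keep <- support >= config$min_support
  n_below <- sum(!keep)
  events <- events[keep]
  ids <- ids[keep]

  variants <- vector("list", length(events))
  n_no_orf <- 0L
  n_identical <- 0L
  for (k in seq_along(events)) {
    e <- events[[k]]
    t <- transcripts[[e$transcript_id]]
    d <- predict_variant_detail(t, e, config)
    if (d$reason == "no_orf") n_no_orf <- n_no_orf + 1L
    else if (d$reason == "identical") n_identical <- n_identical + 1L
    else variants[[k]] <- d$protein
  }
  got <- !vapply(variants, is.null, logical(1))
  variants <- variants[got]
  ids <- ids[got]

  # order by event id, then exact-sequence de-duplication (first id kept)
  o <- order(ids, method = "radix")
  variants <- variants[o]
  ids <- ids[o]
  seqs <- vapply(variants, `[[`, character(1), "sequence")
  dup <- duplicated(seqs)
  duplicates <- list()
  if (any(dup)) {
    for (s in unique(seqs[dup])) {
      grp <- ids[seqs == s]
      duplicates[[grp[1]]] <- grp[-1]
    }
  }
  n_dedup <- sum(dup)
  variants <- variants[!dup]
  ids <- ids[!dup]

  var_headers <- vapply(variants, function(v) encode_header(v$tag),
                        character(1))
  var_seqs <- vapply(variants, `[[`, character(1), "sequence")
  ref_collisions <- var_seqs[var_seqs %in% unname(reference)]

  report <- data.frame(
    stage = c("events_in", "below_support", "no_orf", "identical_product",
              "deduplicated", "variants_kept", "reference_entries",
              "total_entries"),
    count = c(n_events, n_below, n_no_orf, n_identical, n_dedup,
              length(variants), length(reference),
              length(variants) + length(reference)))

  structure(list(
    variants = variants,
    variant_ids = ids,
    headers = c(var_headers, names(reference)),
    sequences = c(stats::setNames(var_seqs, var_headers), reference),
    reference = reference,
    duplicates = duplicates,
    reference_collisions = ref_collisions,
    report = report,
    config = config
  ), class = "variant_db")
}

#' @export
print.variant_db <- function(x, ...) {
  cat("<variant_db>\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Write a database (or any named protein set) as FASTA
#'
#' Residues are emitted uppercase, wrapped at 60 columns, records in
#' database order, so the output is byte-stable.
#'
#' @param db a `variant_db`, or a named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_db_fasta <- function(db, path) {
  seqs <- if (inherits(db, "variant_db")) db$sequences else as_protein_vector(db)
  set <- Biostrings::AAStringSet(toupper(unname(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read a protein FASTA as a named character vector
#'
#' Full description lines are kept as names (variant tags occupy the whole
#' description).
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_proteome_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  v <- as.character(set)
  names(v) <- names(set)
  v
}

#' Write the build report of a database
#'
#' @param db a `variant_db`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_build_report <- function(db, path) {
  stopifnot(inherits(db, "variant_db"))
  utils::write.table(db$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(db$duplicates)) {
    lines <- vapply(names(db$duplicates), function(k) {
      sprintf("# duplicate\t%s\t%s", k,
              paste(db$duplicates[[k]], collapse = ","))
    }, character(1))
    cat(lines, file = path, sep = "\n", append = TRUE)
  }
  invisible(path)
}
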