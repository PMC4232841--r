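# ASE pipeline: consume search-engine peptide tables, call event-supporting
# peptides by the two-stage uniqueness filter, classify alternative
# translation-initiation events, merge result sets from different engines,
# and tabulate event-type frequencies.

#' Parse a peptide identification table
#'
#' Reads the `peptides.txt` dialect (tab-separated; columns `Sequence`,
#' `Proteins`, `Score`, `Intensity`, `Reverse`, `Potential contaminant`;
#' flags are `+`). Any TSV with at least a `Sequence` column is accepted;
#' missing metadata columns are filled with `NA`. Rows flagged as decoy
#' (reverse) or contaminant identifications are removed and the removal
#' counts attached as attributes `n_removed_reverse` /
#' `n_removed_contaminant`.
#'
#' @param x path to a TSV file, or a data frame already read.
#' @param source_engine label recorded on every peptide (e.g.
#'   `"probabilistic"`, `"denovo"`).
#' @return data frame with columns `sequence`, `proteins` (semicolon-joined
#'   accessions or `NA`), `score`, `intensity`, `source_engine`.
#' @export
parse_identifications <- function(x, source_engine = "probabilistic") {
  df <- if (is.character(x)) {
    utils::read.delim(x, sep = "\t", check.names = FALSE,
                      colClasses = "character", comment.char = "")
  } else as.data.frame(x)
  lc <- tolower(names(df))
  pick <- function(nm) {
    k <- which(lc == nm)
    if (length(k)) df[[k[1]]] else rep(NA_character_, nrow(df))
  }
  if (!"sequence" %in% lc) {
    stop("identification table lacks a Sequence column")
  }
  sequence <- toupper(as.character(pick("sequence")))
  reverse <- as.character(pick("reverse"))
  contaminant <- as.character(pick("potential contaminant"))
  is_rev <- !is.na(reverse) & reverse == "+"
  is_con <- !is.na(contaminant) & contaminant == "+" & !is_rev
  out <- data.frame(
    sequence = sequence,
    proteins = as.character(pick("proteins")),
    score = suppressWarnings(as.numeric(pick("score"))),
    intensity = suppressWarnings(as.numeric(pick("intensity"))),
    source_engine = rep(source_engine, nrow(df)))
  out <- out[!(is_rev | is_con), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed_reverse") <- sum(is_rev)
  attr(out, "n_removed_contaminant") <- sum(is_con)
  out
}

#' Is a peptide N-terminal in a protein?
#'
#' A peptide marks the protein's translation start when it begins at residue
#' 1, or — with `nterm_met_cleavage` — at residue 2 of a Met-initiated
#' protein (initiator-Met removal co-occurring with N-terminal processing).
#'
#' @param p a digest row (list/data frame with `start`), or a bare 1-based
#'   start position.
#' @param v a `variant_protein` or amino-acid string.
#' @param nterm_met_cleavage accept the Met-removed position-2 form
#'   (default `TRUE`).
#' @return logical.
#' @export
detect_nterminal <- function(p, v, nterm_met_cleavage = TRUE) {
  start <- if (is.numeric(p)) as.integer(p) else as.integer(p$start[1])
  seq <- if (is.character(v)) v else v$sequence
  if (start == 1L) return(TRUE)
  isTRUE(nterm_met_cleavage) && start == 2L && substr(seq, 1L, 1L) == "M"
}

# Longest common suffix length of two strings.
common_suffix_len <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  n <- min(na, nb)
  if (n == 0L) return(0L)
  av <- substring(a, na - n + 1L, na)
  bv <- substring(b, nb - n + 1L, nb)
  ac <- rev(strsplit(av, "")[[1]])
  bc <- rev(strsplit(bv, "")[[1]])
  mism <- which(ac != bc)
  if (!length(mism)) n else mism[1] - 1L
}

#' Classify the translation-initiation pattern of a variant protein
#'
#' Compares the variant's actual start codon position against the image of
#' the reference start codon under the event's coordinate map:
#'
#' * **C (upstream)** — the reference start survives in the variant mRNA and
#'   the variant initiates upstream of it.
#' * **A (downstream)** — the variant initiates downstream (or the reference
#'   start was deleted), and the variant-specific amino-terminal span is
#'   clear of the event's modified regions.
#' * **B (start affected)** — as A, but the event directly overlaps the new
#'   amino terminus (a codon spanning a pure-deletion junction counts as
#'   overlapping).
#'
#' The variant-specific amino-terminal span runs from the new start codon to
#' the first codon whose residues re-synchronize with the reference protein,
#' determined by the longest common suffix of the two proteins.
#'
#' Additional flags: `first_atg_downstream` is `TRUE` when the variant start
#' is the 5'-most ATG at or after the 3'-most modified-region boundary
#' (frame-agnostic scan unless `first_atg_in_frame` is configured);
#' `wilson_model` is `TRUE` for frame-preserving events whose variant and
#' reference proteins are identical from the first residue encoded
#' downstream of all modified regions through their C-termini — isoforms
#' differing only at the amino end; `orf_disrupting` is its complement.
#'
#' @param v a `variant_protein` carrying `coord_map`, `modified_regions`,
#'   `ref_cds_start`, `tis_mrna_offset`, `variant_mrna`.
#' @param config an [sp_config()].
#' @return list with `tis_category` (`"A"`, `"B"`, `"C"`),
#'   `first_atg_downstream`, `wilson_model`, `orf_disrupting`.
#' @export
classify_tis <- function(v, config = sp_config()) {
  if (is.null(v$coord_map)) {
    stop("variant protein lacks a coordinate map; rebuild it through apply_event")
  }
  s <- as.integer(v$tis_mrna_offset)
  r <- v$coord_map[v$ref_cds_start + 1L]  # image of the reference start
  mr <- v$modified_regions

  # variant-specific N-terminal codon span [s, span_end)
  i0 <- nchar(v$sequence) - common_suffix_len(v$sequence, v$reference_protein) + 1L
  span_end <- s + 3L * max(i0 - 1L, 1L)
  overlaps <- FALSE
  if (nrow(mr)) {
    for (k in seq_len(nrow(mr))) {
      a <- mr$start[k]; b <- mr$end[k]
      hit <- if (b > a) max(s, a) < min(span_end, b) else (s < a && a < span_end)
      if (hit) { overlaps <- TRUE; break }
    }
  }

  category <- if (!is.na(r) && s < r) "C"
    else if ((is.na(r) || s > r) && !overlaps) "A"
    else "B"

  # first-ATG-downstream flag: scan from the 3'-most modified-region boundary
  first_atg <- NA
  if (category != "C" && nrow(mr)) {
    boundary <- max(mr$end)
    tail_seq <- substr(v$variant_mrna, boundary + 1L, nchar(v$variant_mrna))
    hits <- gregexpr("ATG", tail_seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) {
      first_atg <- FALSE
    } else {
      pos <- as.integer(hits) - 1L + boundary
      if (config$first_atg_in_frame) pos <- pos[(pos - s) %% 3L == 0L]
      first_atg <- length(pos) > 0L && pos[1] == s
    }
  }

  wilson <- wilson_model_check(v, i0)
  list(tis_category = category,
       first_atg_downstream = first_atg,
       wilson_model = wilson,
       orf_disrupting = !wilson)
}

# Frame-preserving event + proteins identical from the first residue encoded
# downstream of all modified regions to the C-termini.
wilson_model_check <- function(v, i0) {
  cds_end <- if (!is.null(v$ref_cds_end) && !is.na(v$ref_cds_end)) {
    v$ref_cds_end
  } else v$ref_length
  cds_idx <- (v$ref_cds_start + 1L):cds_end
  mapped <- v$coord_map[cds_idx]
  deleted <- sum(is.na(mapped))  # reference CDS bases removed by the event
  if (all(is.na(mapped))) return(FALSE)
  lo <- min(mapped, na.rm = TRUE)
  hi <- max(mapped, na.rm = TRUE) + 1L
  inserted <- 0L
  mr <- v$modified_regions
  if (nrow(mr)) {
    for (k in seq_len(nrow(mr))) {
      a <- mr$start[k]; b <- mr$end[k]
      if (b > a) inserted <- inserted + max(0L, min(hi, b) - max(lo, a))
    }
  }
  if ((inserted - deleted) %% 3L != 0L) return(FALSE)
  # resynchronization must be reached by the first codon past the event
  boundary <- if (nrow(mr)) max(mr$end) else 0L
  s <- as.integer(v$tis_mrna_offset)
  k_resync <- if (boundary <= s) 1L else ((boundary - s + 2L) %/% 3L) + 1L
  i0 <= max(k_resync, 1L) && i0 <= nchar(v$sequence)
}

#' Call event-supporting peptides
#'
#' Applies the two-stage filter to identified peptides. Stage 1 uses
#' protein-group evidence: a peptide whose accession list contains any
#' non-variant (reference) accession is rejected; when no accession list is
#' present, membership is recomputed by locating the peptide in the
#' database. Stage 2 requires the peptide to be absent from the reference
#' tryptic-peptide universe and not a substring of the matched variant's own
#' template reference protein. Passing peptides are grouped by event;
#' peptides matching several events are attributed to each and flagged
#' shared.
#'
#' @param peptides data frame from [parse_identifications()].
#' @param db a `variant_db` from [build_database()].
#' @param reference_index a `peptide_index` over the same reference proteome
#'   merged into `db`.
#' @param config an [sp_config()].
#' @return data frame of event records (one row per supported event) with
#'   columns `event_id`, `event_type`, `n_peptides`, `peptides`, `is_tis`,
#'   `tis_category`, `first_atg_downstream`, `wilson_model`,
#'   `orf_disrupting`, `source_engines`, `best_score`, `max_intensity`,
#'   `shared_variant_peptides`. Peptides that matched no database entry are
#'   reported in the `unmatched_peptides` attribute.
#' @export
call_ase_support <- function(peptides, db, reference_index,
                             config = sp_config()) {
  stopifnot(inherits(db, "variant_db"), inherits(reference_index, "peptide_index"))
  p <- reference_index$params

  # digest every variant once; index peptide -> variant positions
  n_var <- length(db$variants)
  var_digests <- vector("list", n_var)
  var_pep <- new.env(parent = emptyenv())
  for (k in seq_len(n_var)) {
    dg <- digest(db$variants[[k]]$sequence, max_missed = p$max_missed,
                 min_length = p$min_length, nterm_met = p$nterm_met)
    var_digests[[k]] <- dg
    for (s in unique(dg$sequence)) {
      var_pep[[s]] <- c(var_pep[[s]], k)
    }
  }
  header_to_var <- new.env(parent = emptyenv())
  for (k in seq_len(n_var)) {
    header_to_var[[encode_header(db$variants[[k]]$tag)]] <- k
  }
  ref_headers <- names(db$reference)

  unmatched <- character(0)
  # per-event accumulators
  ev_pep <- list(); ev_engine <- list(); ev_score <- list()
  ev_intens <- list(); ev_var <- list(); ev_shared <- list()

  for (r in seq_len(nrow(peptides))) {
    pep <- peptides$sequence[r]
    accs_raw <- peptides$proteins[r]
    matched <- integer(0)
    if (!is.na(accs_raw) && nzchar(accs_raw)) {
      accs <- strsplit(accs_raw, ";", fixed = TRUE)[[1]]
      dec <- lapply(accs, decode_header)
      if (any(!vapply(dec, `[[`, logical(1), "is_variant"))) next  # stage 1
      idx <- vapply(accs, function(a) {
        v <- header_to_var[[a]]
        if (is.null(v)) NA_integer_ else v
      }, integer(1))
      if (anyNA(idx)) unmatched <- c(unmatched, pep)
      matched <- idx[!is.na(idx)]
    } else {
      if (peptide_in_index(reference_index, pep)) next  # stage 1 recomputed
      matched <- var_pep[[pep]]
      if (is.null(matched)) {
        unmatched <- c(unmatched, pep)
        next
      }
    }
    if (!length(matched)) next
    # stage 2
    if (peptide_in_index(reference_index, pep)) next
    matched <- matched[!vapply(matched, function(k) {
      grepl(pep, db$variants[[k]]$reference_protein, fixed = TRUE)
    }, logical(1))]
    if (!length(matched)) next

    shared <- length(unique(vapply(matched, function(k) {
      db$variants[[k]]$event_ref
    }, character(1)))) > 1L
    for (k in matched) {
      ev <- db$variants[[k]]$event_ref
      ev_pep[[ev]] <- c(ev_pep[[ev]], pep)
      ev_engine[[ev]] <- c(ev_engine[[ev]], peptides$source_engine[r])
      ev_score[[ev]] <- c(ev_score[[ev]], peptides$score[r])
      ev_intens[[ev]] <- c(ev_intens[[ev]], peptides$intensity[r])
      ev_var[[ev]] <- k
      if (shared) ev_shared[[ev]] <- c(ev_shared[[ev]], pep)
    }
  }

  evs <- sort(names(ev_pep))
  rows <- lapply(evs, function(ev) {
    k <- ev_var[[ev]]
    v <- db$variants[[k]]
    peps <- unique(ev_pep[[ev]])
    dg <- var_digests[[k]]
    is_tis <- any(vapply(peps, function(pp) {
      st <- dg$start[dg$sequence == pp]
      length(st) > 0L && detect_nterminal(min(st), v,
        nterm_met_cleavage = TRUE)
    }, logical(1)))
    tis <- if (is_tis) classify_tis(v, config) else
      list(tis_category = NA_character_, first_atg_downstream = NA,
           wilson_model = NA, orf_disrupting = NA)
    sc <- ev_score[[ev]]; it <- ev_intens[[ev]]
    data.frame(
      event_id = ev,
      event_type = v$tag$event_type_code,
      n_peptides = length(peps),
      peptides = paste(peps, collapse = ";"),
      is_tis = is_tis,
      tis_category = tis$tis_category,
      first_atg_downstream = tis$first_atg_downstream,
      wilson_model = tis$wilson_model,
      orf_disrupting = tis$orf_disrupting,
      source_engines = paste(sort(unique(ev_engine[[ev]])), collapse = ";"),
      best_score = if (all(is.na(sc))) NA_real_ else max(sc, na.rm = TRUE),
      max_intensity = if (all(is.na(it))) NA_real_ else max(it, na.rm = TRUE),
      shared_variant_peptides = paste(unique(ev_shared[[ev]]), collapse = ";"))
  })
  out <- if (length(rows)) do.call(rbind, rows) else empty_ase_records()
  rownames(out) <- NULL
  attr(out, "unmatched_peptides") <- unique(unmatched)
  out
}

empty_ase_records <- function() {
  data.frame(event_id = character(0), event_type = character(0),
             n_peptides = integer(0), peptides = character(0),
             is_tis = logical(0), tis_category = character(0),
             first_atg_downstream = logical(0), wilson_model = logical(0),
             orf_disrupting = logical(0), source_engines = character(0),
             best_score = numeric(0), max_intensity = numeric(0),
             shared_variant_peptides = character(0))
}

#' Merge two result sets
#'
#' Unions event records by event id: supporting peptides and source engines
#' are unioned, scores and intensities take the better value. Conflicting
#' event types for one id are an error.
#'
#' @param a,b data frames of event records (see [call_ase_support()]).
#' @return the merged data frame, with a `summary` attribute listing
#'   `n_a`, `n_b`, `n_overlap`, `n_union`.
#' @export
merge_result_sets <- function(a, b) {
  common <- intersect(a$event_id, b$event_id)
  if (length(common)) {
    ta <- a$event_type[match(common, a$event_id)]
    tb <- b$event_type[match(common, b$event_id)]
    bad <- common[ta != tb]
    if (length(bad)) {
      stop("conflicting event_type for event id(s): ",
           paste(bad, collapse = ", "))
    }
  }
  out <- a
  for (ev in b$event_id) {
    j <- which(b$event_id == ev)
    i <- which(out$event_id == ev)
    if (!length(i)) {
      out <- rbind(out, b[j, , drop = FALSE])
    } else {
      peps <- union(strsplit(out$peptides[i], ";")[[1]],
                    strsplit(b$peptides[j], ";")[[1]])
      peps <- peps[nzchar(peps)]
      out$peptides[i] <- paste(peps, collapse = ";")
      out$n_peptides[i] <- length(peps)
      out$source_engines[i] <- paste(
        sort(union(strsplit(out$source_engines[i], ";")[[1]],
                   strsplit(b$source_engines[j], ";")[[1]])), collapse = ";")
      out$is_tis[i] <- out$is_tis[i] | b$is_tis[j]
      if (is.na(out$tis_category[i])) {
        out$tis_category[i] <- b$tis_category[j]
        out$first_atg_downstream[i] <- b$first_atg_downstream[j]
        out$wilson_model[i] <- b$wilson_model[j]
        out$orf_disrupting[i] <- b$orf_disrupting[j]
      }
      out$best_score[i] <- suppressWarnings(
        max(out$best_score[i], b$best_score[j], na.rm = TRUE))
      if (!is.finite(out$best_score[i])) out$best_score[i] <- NA_real_
      out$max_intensity[i] <- suppressWarnings(
        max(out$max_intensity[i], b$max_intensity[j], na.rm = TRUE))
      if (!is.finite(out$max_intensity[i])) out$max_intensity[i] <- NA_real_
    }
  }
  out <- out[order(out$event_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    n_a = nrow(a), n_b = nrow(b),
    n_overlap = length(common),
    n_union = nrow(out))
  out
}

#' Event-type frequency table
#'
#' Counts simple events per type with integer percentages (round half up)
#' over the simple-event total; combined events are counted separately as
#' complex.
#'
#' @param records data frame of event records, or a character vector of
#'   event-type codes.
#' @param config an [sp_config()] supplying the code vocabulary.
#' @return list with `simple` (data frame `event_type`, `count`, `percent`),
#'   `n_simple`, `n_complex`.
#' @export
event_frequency_table <- function(records, config = sp_config()) {
  types <- if (is.data.frame(records)) records$event_type else
    as.character(records)
  case_code <- config$event_codes[["COMBINED"]]
  simple_codes <- unname(config$event_codes[setdiff(names(config$event_codes),
                                                    "COMBINED")])
  is_complex <- types == case_code
  simple <- types[!is_complex]
  counts <- vapply(simple_codes, function(code) sum(simple == code),
                   integer(1))
  total <- sum(counts)
  percent <- if (total > 0L) as.integer(floor(100 * counts / total + 0.5))
    else rep(NA_integer_, length(counts))
  list(simple = data.frame(event_type = simple_codes,
                           count = unname(counts),
                           percent = percent, row.names = NULL),
       n_simple = total,
       n_complex = sum(is_complex))
}

#' Write / read event-record tables
#'
#' Tab-separated, fixed column order, so output is byte-stable.
#'
#' @param records event-record data frame.
#' @param path file path.
#' @return `path` (write) or the records (read).
#' @export
write_ase_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_ase_tsv
#' @export
read_ase_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  for (nm in c("peptides", "source_engines", "shared_variant_peptides")) {
    if (nm %in% names(df)) df[[nm]] <- as.character(df[[nm]])
  }
  df
}
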