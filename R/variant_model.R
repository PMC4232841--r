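# Event-type vocabulary. DUAL_SPECIFIC is part of the taxonomy but event
# generation for it is unsupported (such events are vanishingly rare and
# UTR-confined); it is accepted in tables and counted as zero.
EVENT_TYPES <- c("EXON_SKIP", "ALT_3SS", "ALT_5SS", "INTRON_RETAIN", "DUAL_SPECIFIC")

DEFAULT_EVENT_CODES <- c(
  EXON_SKIP = "ES", ALT_3SS = "A3SS", ALT_5SS = "A5SS",
  INTRON_RETAIN = "IR", DUAL_SPECIFIC = "DS", COMBINED = "CASE"
)

#' Pipeline configuration
#'
#' Collects the tunable switches shared across database construction,
#' digestion and classification. Defaults reproduce the package's reference
#' behaviour: ATG-only initiation with complete (stop-terminated) ORFs,
#' trypsin with no proline restriction, at most two missed cleavages,
#' minimum peptide length 7, and events supported by at least two expressed
#' sequences.
#'
#' @param event_codes named character vector mapping event types
#'   (`EXON_SKIP`, `ALT_3SS`, `ALT_5SS`, `INTRON_RETAIN`, `DUAL_SPECIFIC`,
#'   `COMBINED`) to the short codes used in FASTA header tags.
#' @param min_support minimum number of expressed sequences supporting an
#'   event for it to enter the database (default 2).
#' @param allow_open_ended include ORFs lacking a stop codon before the
#'   sequence end when choosing the largest ORF (default `FALSE`).
#' @param max_missed maximum missed tryptic cleavages (default 2).
#' @param min_length minimum peptide length in residues (default 7).
#' @param nterm_met_cleavage also digest/index the initiator-Met-removed form
#'   of protein N-terminal peptides (default `FALSE`).
#' @param il_equivalence fold I and L together before peptide set comparison
#'   (default `FALSE`).
#' @param substring_mode in [variant_unique_peptides()], additionally reject
#'   peptides occurring as substrings anywhere in the template reference
#'   protein (default `FALSE`; the pipeline-level classifier always applies
#'   the template substring guard).
#' @param first_atg_in_frame restrict the first-ATG-downstream scan to the
#'   variant ORF's frame instead of all frames (default `FALSE`).
#' @return an object of class `sp_config` (a named list).
#' @export
sp_config <- function(event_codes = DEFAULT_EVENT_CODES,
                      min_support = 2L,
                      allow_open_ended = FALSE,
                      max_missed = 2L,
                      min_length = 7L,
                      nterm_met_cleavage = FALSE,
                      il_equivalence = FALSE,
                      substring_mode = FALSE,
                      first_atg_in_frame = FALSE) {
  codes <- DEFAULT_EVENT_CODES
  codes[names(event_codes)] <- event_codes
  bad <- grepl("[#():]", codes)
  if (any(bad)) {
    stop("event codes must not contain '#', '(', ')' or ':': ",
         paste(codes[bad], collapse = ", "))
  }
  structure(list(
    event_codes = codes,
    min_support = as.integer(min_support),
    allow_open_ended = isTRUE(allow_open_ended),
    max_missed = as.integer(max_missed),
    min_length = as.integer(min_length),
    nterm_met_cleavage = isTRUE(nterm_met_cleavage),
    il_equivalence = isTRUE(il_equivalence),
    substring_mode = isTRUE(substring_mode),
    first_atg_in_frame = isTRUE(first_atg_in_frame)
  ), class = "sp_config")
}

#' Read a configuration from a YAML file
#'
#' Recognised keys match the arguments of [sp_config()]; `event_codes` is a
#' mapping from event type to code. Unknown keys are rejected.
#'
#' @param path path to a YAML file.
#' @return an `sp_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sp_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(vals$event_codes)) vals$event_codes <- unlist(vals$event_codes)
  do.call(sp_config, vals)
}

valid_nt <- function(x) {
  all(grepl("^[ACGTN]*$", x))
}

#' Reference transcript model
#'
#' A transcript is an ordered set of exon sequences with the intervening
#' intron sequences and an annotated coding region on the spliced mRNA
#' (0-based, half-open). All coordinates downstream of ingestion live in
#' spliced-mRNA space; genome-backed loaders reverse-complement minus-strand
#' transcripts before constructing this object.
#'
#' @param transcript_id accession string.
#' @param exons character vector of exon sequences, 5' to 3'.
#' @param introns character vector of intron sequences; must have
#'   `length(exons) - 1` elements.
#' @param cds_start 0-based offset of the annotated start codon in the
#'   spliced mRNA, or `NA` when no CDS is annotated.
#' @param cds_end 0-based exclusive offset of the last base of the stop
#'   codon, or `NA`.
#' @param gene_id optional gene symbol/identifier.
#' @return an object of class `transcript`.
#' @export
transcript <- function(transcript_id, exons, introns = character(0),
                       cds_start = NA_integer_, cds_end = NA_integer_,
                       gene_id = NA_character_) {
  exons <- toupper(as.character(exons))
  introns <- toupper(as.character(introns))
  stopifnot(length(exons) >= 1L)
  if (!valid_nt(exons) || !valid_nt(introns)) {
    stop("transcript ", transcript_id, ": sequences must be over {A,C,G,T,N}")
  }
  if (length(introns) != length(exons) - 1L) {
    stop("transcript ", transcript_id, ": need length(exons) - 1 introns, got ",
         length(introns))
  }
  spliced_len <- sum(nchar(exons))
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (!is.na(cds_start)) {
    if (is.na(cds_end)) stop("cds_start given without cds_end")
    if (cds_start < 0L || cds_start >= cds_end || cds_end > spliced_len) {
      stop("transcript ", transcript_id, ": CDS [", cds_start, ", ", cds_end,
           ") out of bounds for spliced length ", spliced_len)
    }
    if ((cds_end - cds_start) %% 3L != 0L) {
      stop("transcript ", transcript_id, ": CDS length not divisible by 3")
    }
  }
  structure(list(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    exons = exons, introns = introns,
    cds_start = cds_start, cds_end = cds_end
  ), class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat("<transcript>", x$transcript_id,
      sprintf("(%d exons, spliced %d nt", length(x$exons), sum(nchar(x$exons))),
      if (!is.na(x$cds_start)) {
        sprintf(", CDS [%d, %d))", x$cds_start, x$cds_end)
      } else ", no CDS)", "\n")
  invisible(x)
}

#' Describe a single alternative-splicing event
#'
#' Event parameters, by type:
#' * `EXON_SKIP`: `skip_from`, `skip_to` — 0-based inclusive contiguous range
#'   of skipped exons.
#' * `ALT_3SS`: `exon`, `shift` — signed acceptor shift in nt; negative
#'   extends the exon 5' into the upstream intron, positive truncates the
#'   exon's 5' end.
#' * `ALT_5SS`: `exon`, `shift` — signed donor shift; positive extends the
#'   exon 3' into the downstream intron, negative truncates the 3' end.
#' * `INTRON_RETAIN`: `intron` — 0-based retained intron index.
#'
#' @param event_id unique event identifier.
#' @param transcript_id accession of the affected transcript.
#' @param event_type one of `EXON_SKIP`, `ALT_3SS`, `ALT_5SS`,
#'   `INTRON_RETAIN`.
#' @param params named list of parameters (see Details).
#' @param support_count number of expressed sequences supporting the event
#'   (must be >= 1).
#' @return an object of class `splice_event`.
#' @export
splice_event <- function(event_id, transcript_id, event_type, params,
                         support_count = 2L) {
  event_type <- match.arg(event_type, EVENT_TYPES)
  if (event_type == "DUAL_SPECIFIC") {
    stop("DUAL_SPECIFIC events are part of the taxonomy but not generatable")
  }
  support_count <- as.integer(support_count)
  if (is.na(support_count) || support_count < 1L) {
    stop("support_count must be >= 1")
  }
  params <- lapply(params, as.integer)
  structure(list(
    event_id = as.character(event_id),
    transcript_id = as.character(transcript_id),
    event_type = event_type, params = params,
    support_count = support_count
  ), class = "splice_event")
}

#' Combine several events on one transcript
#'
#' Constituents must be ordered 5' to 3' by affected exon/intron index and
#' must not claim overlapping regions of the transcript (validated against a
#' transcript by [validate_event()]).
#'
#' @param event_id identifier for the combined event.
#' @param events list of [splice_event()] objects (>= 2) on one transcript.
#' @param support_count supporting expressed-sequence count.
#' @return an object of class `combined_event`.
#' @export
combined_event <- function(event_id, events, support_count = 2L) {
  stopifnot(length(events) >= 2L)
  if (!all(vapply(events, inherits, logical(1), "splice_event"))) {
    stop("all constituents must be splice_event objects")
  }
  tids <- unique(vapply(events, `[[`, character(1), "transcript_id"))
  if (length(tids) != 1L) {
    stop("constituent events span multiple transcripts: ",
         paste(tids, collapse = ", "))
  }
  keys <- vapply(events, event_sort_key, numeric(1))
  if (is.unsorted(keys)) events <- events[order(keys)]
  structure(list(
    event_id = as.character(event_id),
    transcript_id = tids,
    events = events,
    support_count = as.integer(support_count)
  ), class = "combined_event")
}

# 5'->3' ordering key in block space: exon i at 2i, intron i at 2i+1.
event_sort_key <- function(e) {
  switch(e$event_type,
    EXON_SKIP = 2 * e$params$skip_from,
    ALT_3SS = 2 * e$params$exon - 0.5,  # acceptor side precedes the exon
    ALT_5SS = 2 * e$params$exon + 0.5,
    INTRON_RETAIN = 2 * e$params$intron + 1)
}

#' @export
print.splice_event <- function(x, ...) {
  cat("<splice_event>", x$event_id, x$event_type, "on", x$transcript_id,
      paste(names(x$params), unlist(x$params), sep = "=", collapse = " "),
      sprintf("(support %d)\n", x$support_count))
  invisible(x)
}

#' @export
print.combined_event <- function(x, ...) {
  cat("<combined_event>", x$event_id, "on", x$transcript_id,
      sprintf("(%d constituents, support %d)\n", length(x$events),
              x$support_count))
  for (e in x$events) print(e)
  invisible(x)
}

# ---- FASTA header tag codec -------------------------------------------------

#' Variant FASTA header tag
#'
#' Variant database records are tagged `REFSEQ_NAME# (EVENT_TYPE:SPLOOCE_ID)`
#' so that any identified peptide can be traced back to the template
#' accession, the event class, and the event identifier.
#'
#' @param refseq_name template accession.
#' @param event_type_code short event-type code (see [sp_config()]).
#' @param splooce_id event identifier.
#' @return an object of class `header_tag`.
#' @export
header_tag <- function(refseq_name, event_type_code, splooce_id) {
  fields <- list(refseq_name = refseq_name, event_type_code = event_type_code,
                 splooce_id = splooce_id)
  for (nm in names(fields)) {
    v <- as.character(fields[[nm]])
    if (length(v) != 1L || is.na(v) || !nzchar(v)) {
      stop("header tag field '", nm, "' must be a non-empty string")
    }
    if (grepl("[#():]", v)) {
      stop("header tag field '", nm, "' contains a delimiter character: ", v)
    }
  }
  structure(list(refseq_name = as.character(refseq_name),
                 event_type_code = as.character(event_type_code),
                 splooce_id = as.character(splooce_id)),
            class = "header_tag")
}

#' Encode a variant header tag
#'
#' @param tag a [header_tag()].
#' @return the header string `REFSEQ_NAME# (EVENT_TYPE:SPLOOCE_ID)`.
#' @export
#' @examples
#' encode_header(header_tag("NM_000546", "ES", "SP00123"))
encode_header <- function(tag) {
  stopifnot(inherits(tag, "header_tag"))
  sprintf("%s# (%s:%s)", tag$refseq_name, tag$event_type_code, tag$splooce_id)
}

#' Decode a FASTA description line
#'
#' Variant-style headers (`ACC# (TYPE:ID)`) decode to their three fields;
#' any other header — reference proteome records keep their original
#' identifiers — is reported as non-variant with the bare description as
#' accession. A leading `>` is tolerated. The canonical encoding has one
#' space after `#`; zero or more are accepted on decode.
#'
#' @param header a FASTA description line.
#' @return a list with `is_variant`; for variants also a `tag`
#'   ([header_tag()]), otherwise `accession`.
#' @export
decode_header <- function(header) {
  stopifnot(is.character(header), length(header) == 1L)
  h <- sub("^>", "", header)
  if (!grepl("#", h, fixed = TRUE)) {
    return(list(is_variant = FALSE, accession = h))
  }
  m <- regexec("^([^#()]+)# *\\(([^#():]+):([^#():]+)\\)\\s*$", h)
  g <- regmatches(h, m)[[1]]
  if (length(g) != 4L) {
    off <- regexpr("#", h, fixed = TRUE)
    stop("malformed variant header at offset ", off, ": ", h)
  }
  list(is_variant = TRUE,
       tag = header_tag(g[2], g[3], g[4]))
}

# ---- Event validation -------------------------------------------------------

# Block-space resources an event claims; used for combined-event overlap
# checks. A skip claims its exons and interior introns; splice-site shifts
# claim the facing exon end plus the adjoining intron half; retention claims
# the whole intron.
event_resources <- function(e) {
  switch(e$event_type,
    EXON_SKIP = {
      i <- e$params$skip_from; j <- e$params$skip_to
      ex <- unlist(lapply(i:j, function(k) {
        c(sprintf("exonF:%d", k), sprintf("exon5:%d", k), sprintf("exon3:%d", k))
      }))
      if (j > i) ex <- c(ex, sprintf("intron:%d", i:(j - 1L)),
                         sprintf("intron3:%d", i:(j - 1L)),
                         sprintf("intron5:%d", i:(j - 1L)))
      ex
    },
    ALT_3SS = c(sprintf("exon5:%d", e$params$exon),
                sprintf("exonF:%d", e$params$exon),
                sprintf("intron3:%d", e$params$exon - 1L)),
    ALT_5SS = c(sprintf("exon3:%d", e$params$exon),
                sprintf("exonF:%d", e$params$exon),
                sprintf("intron5:%d", e$params$exon)),
    INTRON_RETAIN = sprintf(c("intron:%d", "intron5:%d", "intron3:%d"),
                            e$params$intron))
}

# Resources conflict when they share a token, or when a whole-unit token
# meets a part token of the same unit.
resources_conflict <- function(a, b) {
  if (length(intersect(a, b))) return(TRUE)
  expand <- function(r) {
    whole_e <- sub("^exonF:", "", r[startsWith(r, "exonF:")])
    whole_i <- sub("^intron:", "", r[startsWith(r, "intron:")])
    c(r,
      unlist(lapply(whole_e, function(k) sprintf(c("exon5:%s", "exon3:%s"), k))),
      unlist(lapply(whole_i, function(k) sprintf(c("intron5:%s", "intron3:%s"), k))))
  }
  length(intersect(expand(a), expand(b))) > 0L
}

validate_simple <- function(t, e) {
  v <- character(0)
  n_ex <- length(t$exons)
  n_in <- length(t$introns)
  p <- e$params
  add <- function(msg) v <<- c(v, msg)
  switch(e$event_type,
    EXON_SKIP = {
      i <- p$skip_from; j <- p$skip_to
      if (is.null(i) || is.null(j)) {
        add("EXON_SKIP requires skip_from and skip_to")
      } else if (i < 0L || j >= n_ex || i > j) {
        add(sprintf("EXON_SKIP range [%d, %d] out of bounds for %d exons",
                    i, j, n_ex))
      } else if (j - i + 1L >= n_ex) {
        add("EXON_SKIP cannot remove every exon")
      }
    },
    ALT_3SS = {
      i <- p$exon; s <- p$shift
      if (is.null(i) || is.null(s)) {
        add("ALT_3SS requires exon and shift")
      } else if (i <= 0L || i >= n_ex) {
        add(sprintf("ALT_3SS exon %d invalid (not applicable to exon 0; %d exons)",
                    i, n_ex))
      } else if (s == 0L) {
        add("ALT_3SS shift must be non-zero")
      } else if (s < 0L && -s > nchar(t$introns[i])) {
        add(sprintf("ALT_3SS extension %d exceeds intron %d length %d",
                    -s, i - 1L, nchar(t$introns[i])))
      } else if (s > 0L && s >= nchar(t$exons[i + 1L])) {
        add(sprintf("ALT_3SS truncation %d not smaller than exon %d length %d",
                    s, i, nchar(t$exons[i + 1L])))
      }
    },
    ALT_5SS = {
      i <- p$exon; s <- p$shift
      if (is.null(i) || is.null(s)) {
        add("ALT_5SS requires exon and shift")
      } else if (i < 0L || i >= n_ex - 1L) {
        add(sprintf("ALT_5SS exon %d invalid (not applicable to last exon; %d exons)",
                    i, n_ex))
      } else if (s == 0L) {
        add("ALT_5SS shift must be non-zero")
      } else if (s > 0L && s > nchar(t$introns[i + 1L])) {
        add(sprintf("ALT_5SS extension %d exceeds intron %d length %d",
                    s, i, nchar(t$introns[i + 1L])))
      } else if (s < 0L && -s >= nchar(t$exons[i + 1L])) {
        add(sprintf("ALT_5SS truncation %d not smaller than exon %d length %d",
                    -s, i, nchar(t$exons[i + 1L])))
      }
    },
    INTRON_RETAIN = {
      k <- p$intron
      if (is.null(k)) {
        add("INTRON_RETAIN requires intron")
      } else if (k < 0L || k >= n_in) {
        add(sprintf("INTRON_RETAIN intron %d out of bounds (%d introns)",
                    k, n_in))
      }
    })
  if (e$transcript_id != t$transcript_id) {
    add(sprintf("event targets transcript %s, not %s",
                e$transcript_id, t$transcript_id))
  }
  v
}

#' Validate an event against a transcript
#'
#' Checks every structural invariant of an event (index bounds, shift
#' magnitudes, combined-event non-overlap) against a transcript. Violations
#' are returned as data, never raised, so arbitrary well-typed input can be
#' screened.
#'
#' @param t a [transcript()].
#' @param e a [splice_event()] or [combined_event()].
#' @return character vector of violation messages; empty when valid.
#' @export
validate_event <- function(t, e) {
  stopifnot(inherits(t, "transcript"))
  if (inherits(e, "splice_event")) return(validate_simple(t, e))
  stopifnot(inherits(e, "combined_event"))
  v <- character(0)
  if (length(e$events) < 2L) v <- c(v, "combined event needs >= 2 constituents")
  for (ce in e$events) v <- c(v, validate_simple(t, ce))
  if (!length(v)) {
    res <- lapply(e$events, event_resources)
    n <- length(res)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (resources_conflict(res[[i]], res[[j]]) ||
            intron_extensions_overlap(t, e$events[[i]], e$events[[j]])) {
          v <- c(v, sprintf(
            "constituents %d (%s) and %d (%s) claim overlapping regions",
            i, e$events[[i]]$event_type, j, e$events[[j]]$event_type))
        }
      }
    }
  }
  v
}

# A donor extension (ALT_5SS, shift > 0) and an acceptor extension
# (ALT_3SS, shift < 0) may meet inside one intron; they overlap when the
# two extensions together exceed the intron length.
intron_extensions_overlap <- function(t, a, b) {
  pair <- function(d, ac) {
    d$event_type == "ALT_5SS" && d$params$shift > 0L &&
      ac$event_type == "ALT_3SS" && ac$params$shift < 0L &&
      ac$params$exon == d$params$exon + 1L &&
      d$params$shift - ac$params$shift > nchar(t$introns[d$params$exon + 1L])
  }
  pair(a, b) || pair(b, a)
}

# Event-type code for header tags / reports.
event_code <- function(e, config = sp_config()) {
  if (inherits(e, "combined_event")) {
    return(unname(config$event_codes[["COMBINED"]]))
  }
  unname(config$event_codes[[e$event_type]])
}
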