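# External formats: the event TSV dialect, the sequence-backed transcript
# TSV/FASTA pair, and a genome-backed loader (GTF + genome FASTA) that
# normalizes to the sequence-backed transcript form (minus-strand
# transcripts are reverse-complemented at load; all downstream coordinates
# are 0-based spliced-mRNA positions).

#' Read splice events from TSV
#'
#' Expected columns: `event_id`, `transcript_id`, `event_type`, `params`,
#' `support_count` (tab-separated, header required, `#` comments allowed).
#' `params` is `key=value` pairs joined by `;`:
#'
#' * `EXON_SKIP`: `skip=i-j` (0-based inclusive exon range; `skip=i` for one)
#' * `ALT_3SS` / `ALT_5SS`: `exon=i;shift=s` (signed, e.g. `shift=+3`)
#' * `INTRON_RETAIN`: `intron=k`
#'
#' Combined events use `event_type` `COMBINED` with constituents joined by
#' `|`, each `TYPE:params` with `,` as the inner separator, e.g.
#' `EXON_SKIP:skip=1|INTRON_RETAIN:intron=2`.
#'
#' @param path TSV file path.
#' @return list of [splice_event()] / [combined_event()] objects.
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          colClasses = "character", check.names = FALSE)
  need <- c("event_id", "transcript_id", "event_type", "params",
            "support_count")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("event TSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    type <- df$event_type[i]
    support <- as.integer(df$support_count[i])
    if (type == "COMBINED") {
      parts <- strsplit(df$params[i], "|", fixed = TRUE)[[1]]
      constituents <- lapply(seq_along(parts), function(k) {
        kv <- strsplit(parts[k], ":", fixed = TRUE)[[1]]
        if (length(kv) != 2L) {
          stop("malformed combined constituent: ", parts[k])
        }
        splice_event(sprintf("%s.%d", df$event_id[i], k),
                     df$transcript_id[i], kv[1],
                     parse_event_params(kv[1], gsub(",", ";", kv[2])),
                     support)
      })
      combined_event(df$event_id[i], constituents, support)
    } else {
      splice_event(df$event_id[i], df$transcript_id[i], type,
                   parse_event_params(type, df$params[i]), support)
    }
  })
}

parse_event_params <- function(type, s) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  switch(type,
    EXON_SKIP = {
      rng <- strsplit(vals[["skip"]], "-", fixed = TRUE)[[1]]
      list(skip_from = as.integer(rng[1]),
           skip_to = as.integer(rng[length(rng)]))
    },
    ALT_3SS = ,
    ALT_5SS = list(exon = as.integer(vals[["exon"]]),
                   shift = as.integer(vals[["shift"]])),
    INTRON_RETAIN = list(intron = as.integer(vals[["intron"]])),
    stop("unknown event type in TSV: ", type))
}

format_event_params <- function(e) {
  p <- e$params
  switch(e$event_type,
    EXON_SKIP = if (p$skip_from == p$skip_to) sprintf("skip=%d", p$skip_from)
      else sprintf("skip=%d-%d", p$skip_from, p$skip_to),
    ALT_3SS = ,
    ALT_5SS = sprintf("exon=%d;shift=%+d", p$exon, p$shift),
    INTRON_RETAIN = sprintf("intron=%d", p$intron))
}

#' Write splice events to TSV
#'
#' @param events list of event objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  rows <- vapply(events, function(e) {
    if (inherits(e, "combined_event")) {
      params <- paste(vapply(e$events, function(ce) {
        sprintf("%s:%s", ce$event_type,
                gsub(";", ",", format_event_params(ce)))
      }, character(1)), collapse = "|")
      sprintf("%s\t%s\tCOMBINED\t%s\t%d", e$event_id, e$transcript_id,
              params, e$support_count)
    } else {
      sprintf("%s\t%s\t%s\t%s\t%d", e$event_id, e$transcript_id,
              e$event_type, format_event_params(e), e$support_count)
    }
  }, character(1))
  writeLines(c("event_id\ttranscript_id\tevent_type\tparams\tsupport_count",
               rows), path)
  invisible(path)
}

#' Read sequence-backed transcripts (TSV + FASTA pair)
#'
#' The TSV carries one row per transcript (`transcript_id`, `gene_id`,
#' `cds_start`, `cds_end`; empty CDS fields for non-coding); the FASTA holds
#' exon and intron sequences as records named
#' `<transcript_id>|exon|<index>` / `<transcript_id>|intron|<index>`
#' (0-based indices).
#'
#' @param tsv_path transcript table path.
#' @param fasta_path sequence FASTA path.
#' @return named list of [transcript()] objects.
#' @export
read_transcripts <- function(tsv_path, fasta_path) {
  df <- utils::read.delim(tsv_path, sep = "\t", comment.char = "#",
                          colClasses = "character", check.names = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  keys <- strsplit(names(seqs), "|", fixed = TRUE)
  ids <- vapply(keys, `[`, character(1), 1L)
  kind <- vapply(keys, `[`, character(1), 2L)
  idx <- as.integer(vapply(keys, `[`, character(1), 3L))
  out <- lapply(seq_len(nrow(df)), function(i) {
    tid <- df$transcript_id[i]
    sel_e <- which(ids == tid & kind == "exon")
    sel_i <- which(ids == tid & kind == "intron")
    if (!length(sel_e)) stop("no exon sequences for transcript ", tid)
    exons <- as.character(seqs[sel_e])[order(idx[sel_e])]
    introns <- if (length(sel_i)) {
      as.character(seqs[sel_i])[order(idx[sel_i])]
    } else character(0)
    cs <- df$cds_start[i]; ce <- df$cds_end[i]
    transcript(tid, exons, introns,
               cds_start = if (is.na(cs) || !nzchar(cs)) NA else as.integer(cs),
               cds_end = if (is.na(ce) || !nzchar(ce)) NA else as.integer(ce),
               gene_id = if ("gene_id" %in% names(df)) df$gene_id[i]
                 else NA_character_)
  })
  stats::setNames(out, df$transcript_id)
}

#' Write sequence-backed transcripts (TSV + FASTA pair)
#'
#' Inverse of [read_transcripts()].
#'
#' @param transcripts list of [transcript()] objects.
#' @param tsv_path,fasta_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_transcripts <- function(transcripts, tsv_path, fasta_path) {
  if (inherits(transcripts, "transcript")) transcripts <- list(transcripts)
  rows <- vapply(transcripts, function(t) {
    sprintf("%s\t%s\t%s\t%s", t$transcript_id,
            if (is.na(t$gene_id)) "" else t$gene_id,
            if (is.na(t$cds_start)) "" else t$cds_start,
            if (is.na(t$cds_end)) "" else t$cds_end)
  }, character(1))
  writeLines(c("transcript_id\tgene_id\tcds_start\tcds_end", rows), tsv_path)
  seqs <- character(0)
  for (t in transcripts) {
    nm_e <- sprintf("%s|exon|%d", t$transcript_id, seq_along(t$exons) - 1L)
    seqs[nm_e] <- t$exons
    if (length(t$introns)) {
      nm_i <- sprintf("%s|intron|%d", t$transcript_id,
                      seq_along(t$introns) - 1L)
      seqs[nm_i] <- t$introns
    }
  }
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = fasta_path, width = 60L)
  invisible(list(tsv = tsv_path, fasta = fasta_path))
}

#' Load transcripts from GTF + genome FASTA
#'
#' Builds sequence-backed [transcript()] objects from `exon` and `CDS`
#' features (grouped by `transcript_id`). Exons are ordered 5' to 3' along
#' the transcript; minus-strand sequences are reverse-complemented; introns
#' are the genomic gaps between consecutive exons. The CDS start/end are
#' converted to spliced-mRNA coordinates, with a `stop_codon` feature (when
#' present) appended to the CDS end, GTF-style.
#'
#' @param gtf_path GTF file path.
#' @param genome_path genome FASTA path (chromosome names must match).
#' @return named list of [transcript()] objects.
#' @export
load_transcripts_gtf <- function(gtf_path, genome_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  feat <- as.character(gr$type)
  tid_all <- as.character(gr$transcript_id)
  out <- list()
  for (tid in unique(tid_all[feat == "exon"])) {
    sel <- which(tid_all == tid & feat == "exon")
    ex <- gr[sel]
    strand <- as.character(S4Vectors::runValue(GenomicRanges::strand(ex)))[1]
    o <- order(GenomicRanges::start(ex))
    ex <- ex[o]
    chr <- as.character(GenomicRanges::seqnames(ex))[1]
    if (!chr %in% names(genome)) {
      stop("chromosome ", chr, " absent from the genome FASTA")
    }
    fetch <- function(from, to) {
      as.character(Biostrings::subseq(genome[[chr]], from, to))
    }
    starts <- GenomicRanges::start(ex)
    ends <- GenomicRanges::end(ex)
    exon_seq <- mapply(fetch, starts, ends)
    intron_seq <- if (length(starts) > 1L) {
      mapply(fetch, ends[-length(ends)] + 1L, starts[-1] - 1L)
    } else character(0)
    minus <- strand == "-"
    if (minus) {
      rc <- function(x) {
        as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
      }
      exon_seq <- rev(rc(exon_seq))
      intron_seq <- if (length(intron_seq)) rev(rc(intron_seq)) else character(0)
      starts <- rev(starts); ends <- rev(ends)
    }
    # genomic -> spliced-mRNA coordinate conversion
    exon_len <- nchar(exon_seq)
    cum <- c(0L, cumsum(exon_len))
    g2m <- function(gpos) {
      for (k in seq_along(exon_len)) {
        if (!minus && gpos >= starts[k] && gpos <= ends[k]) {
          return(cum[k] + (gpos - starts[k]))
        }
        if (minus && gpos >= starts[k] && gpos <= ends[k]) {
          return(cum[k] + (ends[k] - gpos))
        }
      }
      NA_integer_
    }
    cds_sel <- which(tid_all == tid & feat == "CDS")
    cds_start <- NA_integer_; cds_end <- NA_integer_
    if (length(cds_sel)) {
      cds <- gr[cds_sel]
      stop_sel <- which(tid_all == tid & feat == "stop_codon")
      gmin <- min(GenomicRanges::start(cds))
      gmax <- max(GenomicRanges::end(cds))
      if (length(stop_sel)) {
        gmin <- min(gmin, GenomicRanges::start(gr[stop_sel]))
        gmax <- max(gmax, GenomicRanges::end(gr[stop_sel]))
      }
      if (minus) {
        cds_start <- g2m(gmax)
        cds_end <- g2m(gmin) + 1L
      } else {
        cds_start <- g2m(gmin)
        cds_end <- g2m(gmax) + 1L
      }
    }
    gene <- as.character(gr$gene_id[sel[1]])
    out[[tid]] <- transcript(tid, exon_seq, intron_seq,
                             cds_start = cds_start, cds_end = cds_end,
                             gene_id = if (length(gene)) gene else NA)
  }
  out
}
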