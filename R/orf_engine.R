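# ORF engine: ab-initio prediction of the largest ATG-initiated open
# reading frame and its translation. Initiation is restricted to ATG;
# ORF length is counted in nucleotides including the stop codon, and ties
# go to the 5'-most start.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Enumerate ATG-initiated open reading frames
#'
#' One ORF per ATG occurrence, extended to the first in-frame stop codon
#' (`has_stop = TRUE`) or, failing that, to the last complete codon before
#' the sequence end. Codons containing N never terminate an ORF: only the
#' literal stop codons TAA/TAG/TGA do.
#'
#' @param seq nucleotide string over \{A,C,G,T,N\}.
#' @return data frame with columns `start` (0-based offset of the A of ATG),
#'   `end` (0-based exclusive), `has_stop`, `length_nt`; zero rows when the
#'   sequence has no ATG.
#' @export
enumerate_orfs <- function(seq) {
  seq <- toupper(seq)
  stopifnot(grepl("^[ACGTN]*$", seq))
  n <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      has_stop = logical(0), length_nt = integer(0))
  if (n < 3L) return(empty)
  starts <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  if (starts[1] == -1L) return(empty)
  starts <- as.integer(starts) - 1L  # 0-based

  # 0-based positions of every stop codon occurrence, any frame
  codons <- substring(seq, 1:(n - 2L), 3:n)
  stop_pos <- which(codons %in% STOP_CODONS) - 1L

  res <- lapply(starts, function(s) {
    frame_stops <- stop_pos[stop_pos > s & (stop_pos - s) %% 3L == 0L]
    if (length(frame_stops)) {
      end <- frame_stops[1] + 3L
      has_stop <- TRUE
    } else {
      end <- s + ((n - s) %/% 3L) * 3L
      has_stop <- FALSE
    }
    c(s, end, has_stop)
  })
  m <- do.call(rbind, res)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             has_stop = as.logical(m[, 3]),
             length_nt = as.integer(m[, 2] - m[, 1]))
}

#' Largest ATG-initiated ORF
#'
#' Maximizes nucleotide length (stop codon included); ties are broken by the
#' 5'-most start. Open-ended ORFs (no stop before the sequence end) are
#' excluded unless `allow_open_ended` is set: a predicted full-length cDNA
#' is expected to encode a complete ORF.
#'
#' @param seq nucleotide string.
#' @param allow_open_ended admit ORFs without a stop codon (default `FALSE`).
#' @return a one-row ORF data frame (see [enumerate_orfs()]), or `NULL` when
#'   no qualifying ORF exists.
#' @export
largest_orf <- function(seq, allow_open_ended = FALSE) {
  orfs <- enumerate_orfs(seq)
  if (!allow_open_ended) orfs <- orfs[orfs$has_stop, , drop = FALSE]
  if (!nrow(orfs)) return(NULL)
  best <- which(orfs$length_nt == max(orfs$length_nt))
  orfs[best[which.min(orfs$start[best])], , drop = FALSE]
}

#' Translate an ORF with the standard genetic code
#'
#' Translates codons from the ORF start up to (and excluding) the stop
#' codon; codons containing N yield X. The codon table is the standard
#' genetic code as shipped by Biostrings.
#'
#' @param seq nucleotide string.
#' @param orf a one-row ORF data frame from [enumerate_orfs()] /
#'   [largest_orf()], or a list with `start`, `end`, `has_stop`.
#' @return amino-acid string (empty when the ORF is just a stop codon).
#' @export
translate_orf <- function(seq, orf) {
  seq <- toupper(seq)
  start <- as.integer(orf$start)
  end <- as.integer(orf$end)
  if ((end - start) %% 3L != 0L || start < 0L || end > nchar(seq)) {
    stop("ORF [", start, ", ", end, ") violates the reading frame for a ",
         nchar(seq), " nt sequence")
  }
  if (substr(seq, start + 1L, start + 3L) != "ATG") {
    stop("ORF does not begin with ATG at offset ", start)
  }
  cod_end <- if (isTRUE(orf$has_stop)) end - 3L else end
  translate_codons(substr(seq, start + 1L, cod_end))
}

# Frame-0 translation of a codon-aligned nucleotide string.
translate_codons <- function(nt) {
  n <- nchar(nt)
  if (n == 0L) return("")
  stopifnot(n %% 3L == 0L)
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

# Translation of a transcript's annotated CDS (stop codon excluded).
reference_protein <- function(t) {
  if (is.na(t$cds_start)) stop("transcript ", t$transcript_id, " has no CDS")
  mrna <- splice_reference(t)
  cds <- substr(mrna, t$cds_start + 1L, t$cds_end)
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (last %in% STOP_CODONS) cds <- substr(cds, 1L, nchar(cds) - 3L)
  translate_codons(cds)
}
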