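# Test helpers: case generators and brute-force oracles that are
# independent of the engine code paths they check.

# Random toy transcript with small exons/introns (uses the caller's RNG).
make_toy_transcript <- function(n_exons = NULL, exon_len = c(3L, 60L),
                                intron_len = c(3L, 30L), id = "TOY") {
  if (is.null(n_exons)) n_exons <- sample(2:8, 1L)
  rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
  exons <- vapply(seq_len(n_exons), function(i) {
    rand_nt(sample(exon_len[1]:exon_len[2], 1L))
  }, character(1))
  introns <- vapply(seq_len(n_exons - 1L), function(i) {
    rand_nt(sample(intron_len[1]:intron_len[2], 1L))
  }, character(1))
  transcript(id, exons, introns)
}

# Random valid event (simple or combined) for a transcript.
random_valid_event <- function(t, id = "EV1", p_combined = 0.25) {
  types <- c("EXON_SKIP", "ALT_3SS", "ALT_5SS", "INTRON_RETAIN")
  if (length(t$exons) >= 3L && stats::runif(1) < p_combined) {
    e <- spliceptide:::random_combined(t, id, support_count = 2L)
    if (!is.null(e)) return(e)
  }
  for (i in 1:50) {
    e <- spliceptide:::random_event(t, sample(types, 1L), id,
                                    support_count = 2L)
    if (!is.null(e)) return(e)
  }
  NULL
}

# Brute-force ORF enumeration: for every position with ATG, step codons to
# the first stop (or the last complete codon).
brute_force_orfs <- function(seq) {
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  p <- 1L
  while (p + 2L <= n) {
    if (substr(seq, p, p + 2L) == "ATG") {
      q <- p
      has_stop <- FALSE
      while (q + 2L <= n) {
        if (substr(seq, q, q + 2L) %in% stops) {
          has_stop <- TRUE
          break
        }
        q <- q + 3L
      }
      end <- if (has_stop) q + 2L else q - 1L
      out[[length(out) + 1L]] <- data.frame(
        start = p - 1L, end = end, has_stop = has_stop,
        length_nt = end - p + 1L)
    }
    p <- p + 1L
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      has_stop = logical(0), length_nt = integer(0)))
  }
  do.call(rbind, out)
}

random_protein <- function(len) {
  # alphabet weighted toward K/R so cleavage structure is exercised
  aa <- c(strsplit("ACDEFGHILMNPQSTVWY", "")[[1]], "K", "K", "R", "R")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# Tiny deterministic fixture used by several pipeline tests: a transcript
# whose middle-exon skip turns MAAEEFFKGGHHIIKLLMMNNR into
# MAAKGGHHIIKLLMMNNR.
uniqueness_toy <- function() {
  exons <- c("ATGGCTGCT",                       # M A A
             "GAAGAGTTTTTC",                    # E E F F
             paste0("AAAGGAGGACACCATATCATTAAACTGCTTATGATGAACAATAGA",
                    "TAA"))                     # K G G H H I I K L L M M N N R *
  t <- transcript("NM_TOY1", exons, introns = c("GTCCAG", "GTTTAG"),
                  cds_start = 0L, cds_end = sum(nchar(exons)))
  e <- splice_event("SP001", "NM_TOY1", "EXON_SKIP",
                    list(skip_from = 1L, skip_to = 1L), support_count = 3L)
  list(transcript = t, event = e)
}
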