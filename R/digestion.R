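# In-silico tryptic digestion and reference-proteome peptide indexing.
# Trypsin is modelled with no proline restriction: cleavage occurs after
# every K or R, including K/R-P bonds. Defaults mirror a typical search
# configuration: minimum peptide length 7, at most two missed cleavages.

#' Tryptic cleavage sites
#'
#' @param protein amino-acid string (20-letter alphabet plus X).
#' @return 1-based residue positions after which cleavage occurs: every K or
#'   R except a protein-C-terminal one. No proline restriction — a following
#'   P does not suppress the site.
#' @export
cleavage_sites <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L, nzchar(protein))
  res <- strsplit(protein, "")[[1]]
  pos <- which(res %in% c("K", "R"))
  pos[pos < length(res)]
}

#' In-silico tryptic digest
#'
#' Enumerates every peptide spanning at most `max_missed` internal cleavage
#' sites, filtered to `min_length` residues, sorted by start position then
#' length. With `nterm_met` set, proteins starting with M additionally
#' contribute the initiator-Met-removed form of each N-terminal peptide
#' (start position 2, flagged `met_removed`), reflecting searches that allow
#' protein N-terminal processing.
#'
#' @param protein amino-acid string.
#' @param max_missed maximum missed cleavages (default 2).
#' @param min_length minimum peptide length (default 7).
#' @param nterm_met also emit Met-removed N-terminal peptides (default
#'   `FALSE`).
#' @return data frame with columns `sequence`, `start` (1-based), `missed`,
#'   `met_removed`.
#' @export
digest <- function(protein, max_missed = 2L, min_length = 7L,
                   nterm_met = FALSE) {
  stopifnot(is.character(protein), length(protein) == 1L, nzchar(protein))
  n <- nchar(protein)
  bounds <- c(0L, cleavage_sites(protein), n)  # peptide boundaries
  k <- length(bounds)
  out <- list()
  for (i in seq_len(k - 1L)) {
    jmax <- min(i + 1L + max_missed, k)
    for (j in (i + 1L):jmax) {
      len <- bounds[j] - bounds[i]
      if (len < min_length) next
      out[[length(out) + 1L]] <- list(
        sequence = substr(protein, bounds[i] + 1L, bounds[j]),
        start = bounds[i] + 1L,
        missed = j - i - 1L,
        met_removed = FALSE)
    }
  }
  if (isTRUE(nterm_met) && substr(protein, 1L, 1L) == "M" && n > 1L) {
    jmax <- min(2L + max_missed, k)
    for (j in 2L:jmax) {
      len <- bounds[j] - 1L
      if (len < min_length) next
      out[[length(out) + 1L]] <- list(
        sequence = substr(protein, 2L, bounds[j]),
        start = 2L,
        missed = j - 2L,
        met_removed = TRUE)
    }
  }
  if (!length(out)) {
    return(data.frame(sequence = character(0), start = integer(0),
                      missed = integer(0), met_removed = logical(0)))
  }
  df <- data.frame(
    sequence = vapply(out, `[[`, character(1), "sequence"),
    start = vapply(out, function(x) as.integer(x$start), integer(1)),
    missed = vapply(out, function(x) as.integer(x$missed), integer(1)),
    met_removed = vapply(out, `[[`, logical(1), "met_removed"))
  df <- df[order(df$start, nchar(df$sequence), df$met_removed), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Index the tryptic-peptide universe of a proteome
#'
#' Digests every record and maps each peptide sequence to the set of
#' (accession, start) occurrences, so membership queries ("does this peptide
#' exist anywhere in the reference proteome as a tryptic peptide?") are
#' constant-time. Digestion parameters are stored with the index and checked
#' by consumers.
#'
#' @param proteome named character vector of protein sequences (names are
#'   accessions), or a `Biostrings::AAStringSet`.
#' @param max_missed,min_length,nterm_met digestion parameters, see
#'   [digest()].
#' @param il_equivalence fold I/L to a common letter in index keys (default
#'   `FALSE`).
#' @return an object of class `peptide_index`.
#' @export
build_peptide_index <- function(proteome, max_missed = 2L, min_length = 7L,
                                nterm_met = FALSE, il_equivalence = FALSE) {
  proteome <- as_protein_vector(proteome)
  if (anyDuplicated(names(proteome))) {
    stop("duplicate accessions in proteome: ",
         paste(unique(names(proteome)[duplicated(names(proteome))]),
               collapse = ", "))
  }
  env <- new.env(parent = emptyenv(), size = max(16L, 2L * length(proteome)))
  for (acc in names(proteome)) {
    pep <- digest(proteome[[acc]], max_missed = max_missed,
                  min_length = min_length, nterm_met = nterm_met)
    if (!nrow(pep)) next
    keys <- pep$sequence
    if (il_equivalence) keys <- fold_il(keys)
    for (r in seq_len(nrow(pep))) {
      key <- keys[r]
      hit <- data.frame(accession = acc, start = pep$start[r])
      env[[key]] <- if (is.null(env[[key]])) hit else rbind(env[[key]], hit)
    }
  }
  structure(list(
    table = env,
    n_proteins = length(proteome),
    params = list(max_missed = as.integer(max_missed),
                  min_length = as.integer(min_length),
                  nterm_met = isTRUE(nterm_met),
                  il_equivalence = isTRUE(il_equivalence))
  ), class = "peptide_index")
}

fold_il <- function(x) gsub("I", "L", x, fixed = TRUE)

#' Query a peptide index
#'
#' @param index a `peptide_index`.
#' @param peptides character vector of peptide sequences.
#' @return logical vector: is each peptide present in the indexed tryptic
#'   universe?
#' @export
peptide_in_index <- function(index, peptides) {
  stopifnot(inherits(index, "peptide_index"))
  if (index$params$il_equivalence) peptides <- fold_il(peptides)
  vapply(peptides, function(p) !is.null(index$table[[p]]), logical(1),
         USE.NAMES = FALSE)
}

#' Occurrences of a peptide in the indexed proteome
#'
#' @param index a `peptide_index`.
#' @param peptide one peptide sequence.
#' @return data frame of `accession`, `start` (empty when absent).
#' @export
peptide_occurrences <- function(index, peptide) {
  stopifnot(inherits(index, "peptide_index"), length(peptide) == 1L)
  if (index$params$il_equivalence) peptide <- fold_il(peptide)
  hit <- index$table[[peptide]]
  if (is.null(hit)) data.frame(accession = character(0), start = integer(0))
  else hit
}

#' @export
print.peptide_index <- function(x, ...) {
  cat(sprintf("<peptide_index> %d proteins, %d distinct peptides (missed <= %d, length >= %d)\n",
              x$n_proteins, length(ls(x$table)), x$params$max_missed,
              x$params$min_length))
  invisible(x)
}

#' Variant-unique tryptic peptides
#'
#' Digests a variant protein and removes every peptide present in the
#' reference tryptic universe. In strict substring mode, peptides occurring
#' anywhere inside the variant's own template reference protein are also
#' rejected, guarding against semi-tryptic coincidences.
#'
#' @param v a `variant_protein` (see [predict_variant_protein()]), or a bare
#'   amino-acid string.
#' @param reference_index a `peptide_index` over the reference proteome.
#' @param substring_mode also reject substrings of the template reference
#'   protein (default `FALSE`); requires `v` to carry `reference_protein`.
#' @return data frame of unique peptides (columns as [digest()]).
#' @export
variant_unique_peptides <- function(v, reference_index,
                                    substring_mode = FALSE) {
  stopifnot(inherits(reference_index, "peptide_index"))
  seq <- if (is.character(v)) v else v$sequence
  p <- reference_index$params
  pep <- digest(seq, max_missed = p$max_missed, min_length = p$min_length,
                nterm_met = p$nterm_met)
  if (!nrow(pep)) return(pep)
  keep <- !peptide_in_index(reference_index, pep$sequence)
  if (isTRUE(substring_mode)) {
    if (is.character(v) || is.null(v$reference_protein)) {
      stop("substring_mode requires a variant protein carrying its template")
    }
    keep <- keep & !vapply(pep$sequence, grepl, logical(1),
                           x = v$reference_protein, fixed = TRUE,
                           USE.NAMES = FALSE)
  }
  out <- pep[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Coerce AAStringSet / list / character to a named character vector,
# keeping full description lines as names.
as_protein_vector <- function(x) {
  if (inherits(x, "AAStringSet")) {
    v <- as.character(x)
    names(v) <- names(x)
    return(v)
  }
  if (is.list(x)) x <- unlist(x)
  stopifnot(is.character(x))
  if (is.null(names(x))) stop("proteome must carry accessions as names")
  x
}
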