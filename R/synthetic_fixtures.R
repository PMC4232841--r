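# Synthetic fixtures: seeded generators for toy genes, splice events,
# variant databases and peptide-observation tables, with ground truth
# computed by an independent oracle (per-base inclusion flags over the
# pre-mRNA, naive ATG->stop scanning, brute-force digestion) rather than by
# the splice/ORF/digestion engines, so the pipeline can be cross-validated
# end to end.

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483646L))
  force(code)
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483629)
}

random_nt <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Remove every ATG trinucleotide from a sequence (overlap-safe).
scrub_atg <- function(seq) {
  while (grepl("ATG", seq, fixed = TRUE)) {
    seq <- sub("ATG", "ATC", seq, fixed = TRUE)
  }
  seq
}

# Replace stop codons (and optionally K/R codons) at in-frame positions of
# seq starting at `frame_from` (0-based) with a proline codon. The
# replacement never creates ATG or stop codons in any overlapping frame
# ("CCC" is additionally K/R-safe in its own frame).
scrub_codons <- function(seq, frame_from, to = nchar(seq),
                         also_kr = FALSE, repl = "CCT") {
  bad <- c(STOP_CODONS, if (also_kr) c("AAA", "AAG", "AGA", "AGG",
                                       "CGA", "CGC", "CGG", "CGT"))
  p <- frame_from
  while (p + 3L <= to) {
    cod <- substr(seq, p + 1L, p + 3L)
    if (cod %in% bad) {
      substr(seq, p + 1L, p + 3L) <- repl
    }
    p <- p + 3L
  }
  seq
}

#' Generate a random toy gene
#'
#' Random exon/intron sequences with an ATG written at a sampled CDS start
#' and an in-frame stop codon placed in the final exon; premature in-frame
#' stop codons inside the CDS are recoded so the annotated CDS translates
#' cleanly. Deterministic under `seed`.
#'
#' @param seed integer seed.
#' @param n_exons exon count (2-10); sampled when `NULL`.
#' @param exon_len length-2 range of exon lengths in nt (30-120).
#' @param intron_len length-2 range of intron lengths in nt (9-60).
#' @param gc GC content (0.2-0.8).
#' @param transcript_id accession for the new transcript.
#' @return a [transcript()].
#' @export
generate_gene <- function(seed, n_exons = NULL, exon_len = c(30L, 120L),
                          intron_len = c(9L, 60L), gc = 0.5,
                          transcript_id = "TX0001") {
  stopifnot(gc >= 0.2, gc <= 0.8)
  with_seed(seed, {
    if (is.null(n_exons)) n_exons <- sample(2:10, 1L)
    stopifnot(n_exons >= 2L, n_exons <= 10L)
    exons <- vapply(seq_len(n_exons), function(i) {
      random_nt(sample(exon_len[1]:exon_len[2], 1L), gc)
    }, character(1))
    introns <- vapply(seq_len(n_exons - 1L), function(i) {
      random_nt(sample(intron_len[1]:intron_len[2], 1L), gc)
    }, character(1))
    finish_gene(transcript_id, exons, introns)
  })
}

# Shared tail of gene construction: pick cds_start (not in the final exon),
# write the start codon, recode premature stops, place the stop codon in the
# final exon. Uses the caller's RNG stream.
finish_gene <- function(transcript_id, exons, introns,
                        cds_start = NULL) {
  exon_len <- nchar(exons)
  last_start <- sum(exon_len) - exon_len[length(exons)]
  mrna <- paste(exons, collapse = "")
  for (attempt in seq_len(50L)) {
    cs <- if (is.null(cds_start)) {
      sample(0:(last_start - 3L), 1L)
    } else cds_start
    # stop codon at an in-frame position inside the final exon, leaving a
    # 3' UTR when room permits
    cand <- seq.int(cs, sum(exon_len) - 3L, by = 3L)
    cand <- cand[cand >= last_start & cand + 3L <= sum(exon_len)]
    if (!length(cand)) {
      if (!is.null(cds_start)) stop("no in-frame stop position in final exon")
      next
    }
    stop_pos <- cand[min(length(cand), max(1L, length(cand) %/% 2L))]
    substr(mrna, cs + 1L, cs + 3L) <- "ATG"
    mrna <- scrub_codons(mrna, cs, to = stop_pos)
    substr(mrna, stop_pos + 1L, stop_pos + 3L) <- "TAA"
    # rebuild exon sequences from the edited mRNA
    bounds <- c(0L, cumsum(exon_len))
    exons <- vapply(seq_along(exons), function(i) {
      substr(mrna, bounds[i] + 1L, bounds[i + 1L])
    }, character(1))
    return(transcript(transcript_id, exons, introns,
                      cds_start = cs, cds_end = stop_pos + 3L))
  }
  stop("gene generation failed after bounded retries")
}

# ---- Independent oracle -----------------------------------------------------

# Oracle event application: per-base inclusion flags over the pre-mRNA.
# Returns sequence, coord_map, modified_regions exactly as the contract
# defines them, computed without the splice engine.
oracle_apply <- function(t, e) {
  events <- if (inherits(e, "combined_event")) e$events else list(e)
  n_ex <- length(t$exons)
  kind <- integer(0); ref_pos <- integer(0); base <- character(0)
  incl <- logical(0)
  rp <- 0L
  for (i in seq_len(n_ex)) {
    bs <- strsplit(t$exons[i], "")[[1]]
    kind <- c(kind, rep(i, length(bs)))          # exon i (1-based)
    ref_pos <- c(ref_pos, seq.int(rp, length.out = length(bs)))
    base <- c(base, bs)
    incl <- c(incl, rep(TRUE, length(bs)))
    rp <- rp + length(bs)
    if (i < n_ex) {
      ibs <- strsplit(t$introns[i], "")[[1]]
      kind <- c(kind, rep(-i, length(ibs)))      # intron i (1-based, negative)
      ref_pos <- c(ref_pos, rep(NA_integer_, length(ibs)))
      base <- c(base, ibs)
      incl <- c(incl, rep(FALSE, length(ibs)))
    }
  }
  grp <- rep(NA_character_, length(base))  # distinguishes insertion sources
  for (gi in seq_along(events)) {
    ev <- events[[gi]]
    p <- ev$params
    switch(ev$event_type,
      EXON_SKIP = {
        incl[kind %in% ((p$skip_from:p$skip_to) + 1L)] <- FALSE
      },
      INTRON_RETAIN = {
        w <- which(kind == -(p$intron + 1L))
        incl[w] <- TRUE
        grp[w] <- sprintf("g%d", gi)
      },
      ALT_3SS = {
        if (p$shift < 0L) {
          w <- which(kind == -p$exon)            # upstream intron
          w <- w[(length(w) + p$shift + 1L):length(w)]
          incl[w] <- TRUE
          grp[w] <- sprintf("g%d", gi)
        } else {
          w <- which(kind == p$exon + 1L)
          incl[w[1:p$shift]] <- FALSE
        }
      },
      ALT_5SS = {
        if (p$shift > 0L) {
          w <- which(kind == -(p$exon + 1L))     # downstream intron
          w <- w[1:p$shift]
          incl[w] <- TRUE
          grp[w] <- sprintf("g%d", gi)
        } else {
          w <- which(kind == p$exon + 1L)
          incl[w[(length(w) + p$shift + 1L):length(w)]] <- FALSE
        }
      })
  }
  coord_map <- rep(NA_integer_, rp)
  regions <- list()
  var_pos <- 0L
  pending <- FALSE
  reg_open <- NA_integer_
  reg_grp <- NA_character_
  for (k in seq_along(base)) {
    if (incl[k]) {
      if (!is.na(ref_pos[k])) {                  # reference (exonic) base
        if (!is.na(reg_open)) {
          regions[[length(regions) + 1L]] <- c(reg_open, var_pos)
          reg_open <- NA_integer_
        }
        if (pending) {
          regions[[length(regions) + 1L]] <- c(var_pos, var_pos)
          pending <- FALSE
        }
        coord_map[ref_pos[k] + 1L] <- var_pos
      } else {                                   # inserted (intronic) base
        if (!is.na(reg_open) && !identical(grp[k], reg_grp)) {
          regions[[length(regions) + 1L]] <- c(reg_open, var_pos)
          reg_open <- NA_integer_
        }
        if (is.na(reg_open)) {
          reg_open <- var_pos
          reg_grp <- grp[k]
          pending <- FALSE                       # insertion covers the junction
        }
      }
      var_pos <- var_pos + 1L
    } else if (!is.na(ref_pos[k])) {             # deleted reference base
      if (!is.na(reg_open)) {                    # close the insertion run
        regions[[length(regions) + 1L]] <- c(reg_open, var_pos)
        reg_open <- NA_integer_
      }
      pending <- TRUE
    }
  }
  if (!is.na(reg_open)) {
    regions[[length(regions) + 1L]] <- c(reg_open, var_pos)
  }
  if (pending) regions[[length(regions) + 1L]] <- c(var_pos, var_pos)
  if (length(regions)) {
    m <- do.call(rbind, regions)
    mr <- unique(data.frame(start = m[, 1], end = m[, 2]))
    mr <- mr[order(mr$start, mr$end), , drop = FALSE]
    rownames(mr) <- NULL
  } else {
    mr <- data.frame(start = integer(0), end = integer(0))
  }
  list(sequence = paste(base[incl], collapse = ""),
       coord_map = coord_map,
       modified_regions = mr,
       ref_length = rp)
}

# Oracle ORF finder: naive per-position ATG scan with codon stepping.
oracle_largest_orf <- function(seq, allow_open_ended = FALSE) {
  n <- nchar(seq)
  best <- NULL
  for (p in seq_len(max(n - 2L, 0L))) {
    if (substr(seq, p, p + 2L) != "ATG") next
    q <- p
    has_stop <- FALSE
    while (q + 2L <= n) {
      if (substr(seq, q, q + 2L) %in% STOP_CODONS) { has_stop <- TRUE; break }
      q <- q + 3L
    }
    end <- if (has_stop) q + 2L else q - 1L
    if (!has_stop && !allow_open_ended) next
    len <- end - p + 1L
    if (is.null(best) || len > best$length_nt) {
      best <- list(start = p - 1L, end = end, has_stop = has_stop,
                   length_nt = len)
    }
  }
  best
}

# Oracle translation: codon loop over the standard code table.
oracle_translate <- function(seq, from, to) {
  out <- character(0)
  p <- from
  while (p + 3L <= to) {
    cod <- substr(seq, p + 1L, p + 3L)
    aa <- Biostrings::GENETIC_CODE[[cod]]
    if (is.null(aa) || is.na(aa)) aa <- "X"
    out <- c(out, aa)
    p <- p + 3L
  }
  paste(out, collapse = "")
}

# Oracle digestion: brute force over all (start, end) residue pairs.
oracle_digest <- function(protein, max_missed = 2L, min_length = 7L) {
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  is_site <- res %in% c("K", "R")
  out <- list()
  for (a in seq_len(n)) {
    if (a > 1L && !is_site[a - 1L]) next      # must start after a site
    for (b in a:n) {
      if (b < n && !is_site[b]) next          # must end at a site or C-term
      if (b - a + 1L < min_length) next
      internal <- if (b > a) sum(is_site[a:(b - 1L)]) else 0L
      if (internal > max_missed) next
      out[[length(out) + 1L]] <- list(
        sequence = paste(res[a:b], collapse = ""), start = a,
        missed = internal)
    }
  }
  if (!length(out)) {
    return(data.frame(sequence = character(0), start = integer(0),
                      missed = integer(0)))
  }
  data.frame(sequence = vapply(out, `[[`, character(1), "sequence"),
             start = vapply(out, function(x) as.integer(x$start), integer(1)),
             missed = vapply(out, function(x) as.integer(x$missed),
                             integer(1)))
}

# Oracle variant-protein prediction; returns NULL when no qualifying or no
# altered product exists, mirroring the selection filter.
oracle_variant_protein <- function(t, e) {
  va <- oracle_apply(t, e)
  orf <- oracle_largest_orf(va$sequence)
  if (is.null(orf)) return(NULL)
  prot <- oracle_translate(va$sequence, orf$start, orf$end - 3L)
  if (!nzchar(prot)) return(NULL)
  ref_cds <- substr(paste(t$exons, collapse = ""), t$cds_start + 1L,
                    t$cds_end - 3L)
  ref_prot <- oracle_translate(ref_cds, 0L, nchar(ref_cds))
  if (identical(prot, ref_prot)) return(NULL)
  structure(list(
    sequence = prot,
    tis_mrna_offset = orf$start,
    orf_end = orf$end,
    variant_mrna = va$sequence,
    reference_protein = ref_prot,
    ref_cds_start = t$cds_start,
    ref_cds_end = t$cds_end,
    event_ref = e$event_id,
    source_transcript_id = t$transcript_id,
    modified_regions = va$modified_regions,
    coord_map = va$coord_map,
    ref_length = va$ref_length
  ), class = "variant_protein")
}

# ---- Event generation -------------------------------------------------------

# One random valid event of a requested type on t (caller's RNG stream);
# NULL when no valid parameterization was found within bounded retries.
random_event <- function(t, type, event_id, support_count) {
  n_ex <- length(t$exons)
  for (i in seq_len(30L)) {
    e <- switch(type,
      EXON_SKIP = {
        from <- sample(0:(n_ex - 1L), 1L)
        to <- min(n_ex - 1L, from + sample(0:2, 1L, prob = c(.7, .2, .1)))
        if (to - from + 1L >= n_ex) next
        splice_event(event_id, t$transcript_id, "EXON_SKIP",
                     list(skip_from = from, skip_to = to), support_count)
      },
      ALT_3SS = {
        if (n_ex < 2L) next
        ex <- sample(1:(n_ex - 1L), 1L)
        ext_max <- nchar(t$introns[ex])
        tr_max <- nchar(t$exons[ex + 1L]) - 1L
        shift <- sample(c(-seq_len(min(ext_max, 15L)),
                          seq_len(min(tr_max, 15L))), 1L)
        splice_event(event_id, t$transcript_id, "ALT_3SS",
                     list(exon = ex, shift = shift), support_count)
      },
      ALT_5SS = {
        if (n_ex < 2L) next
        ex <- sample(0:(n_ex - 2L), 1L)
        ext_max <- nchar(t$introns[ex + 1L])
        tr_max <- nchar(t$exons[ex + 1L]) - 1L
        shift <- sample(c(seq_len(min(ext_max, 15L)),
                          -seq_len(min(tr_max, 15L))), 1L)
        splice_event(event_id, t$transcript_id, "ALT_5SS",
                     list(exon = ex, shift = shift), support_count)
      },
      INTRON_RETAIN = {
        splice_event(event_id, t$transcript_id, "INTRON_RETAIN",
                     list(intron = sample(0:(n_ex - 2L), 1L)), support_count)
      })
    if (!length(validate_event(t, e))) return(e)
  }
  NULL
}

#' Generate random valid events for a transcript
#'
#' Samples event types from `mix` (defaults echo transcriptome-wide
#' proportions of 35/29/25/11 percent for skipping, alternative 3'/5' sites
#' and retention; `COMBINED` weight 0) and valid parameters by bounded
#' rejection. Support counts are sampled >= 2. Deterministic under `seed`.
#'
#' @param t a [transcript()].
#' @param n number of events.
#' @param mix named weights over `EXON_SKIP`, `ALT_3SS`, `ALT_5SS`,
#'   `INTRON_RETAIN`, `COMBINED`.
#' @param seed integer seed.
#' @param id_prefix prefix for generated event ids.
#' @return list of event objects (may be shorter than `n` when a sampled
#'   type admits no valid event on `t`).
#' @export
generate_events <- function(t, n, mix = c(EXON_SKIP = 35, ALT_3SS = 29,
                                          ALT_5SS = 25, INTRON_RETAIN = 11,
                                          COMBINED = 0),
                            seed = 1L, id_prefix = "EV") {
  with_seed(seed, {
    types <- sample(names(mix), n, replace = TRUE, prob = mix)
    out <- list()
    for (k in seq_len(n)) {
      eid <- sprintf("%s%05d", id_prefix, k)
      support <- sample(2:50, 1L)
      if (types[k] == "COMBINED") {
        e <- random_combined(t, eid, support)
      } else {
        e <- random_event(t, types[k], eid, support)
      }
      if (is.null(e)) {
        warning("no valid ", types[k], " event for ", t$transcript_id)
        next
      }
      out[[length(out) + 1L]] <- e
    }
    out
  })
}

random_combined <- function(t, event_id, support_count) {
  simple <- c("EXON_SKIP", "ALT_3SS", "ALT_5SS", "INTRON_RETAIN")
  for (i in seq_len(30L)) {
    k <- sample(2:3, 1L, prob = c(.8, .2))
    parts <- lapply(seq_len(k), function(j) {
      random_event(t, sample(simple, 1L), sprintf("%s.%d", event_id, j),
                   support_count)
    })
    if (any(vapply(parts, is.null, logical(1)))) next
    ce <- combined_event(event_id, parts, support_count)
    if (!length(validate_event(t, ce))) return(ce)
  }
  NULL
}
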