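# Fixture-set assembly: whole synthetic studies (genes + events + reference
# proteome + ground truth), including a TIS-rich preset whose engineered
# genes guarantee that all three alternative-TIS categories occur, and the
# peptide-observation simulator that emulates a filtered search-engine
# peptide table.

# ---- TIS-rich engineered genes ---------------------------------------------

# Gene skeleton for TIS engineering: 4 exons, CDS starting inside exon 1
# (0-based) and ending in exon 3. All ATGs outside the annotated start are
# scrubbed so the largest variant ORF is fully determined by construction.
# `flavor` decides which alternative-TIS category the paired event will
# produce: "downstream" (exon-skip -> category A), "start_hit" (CDS intron
# retention -> category B), "upstream" (5'UTR intron retention -> category C).
tis_gene <- function(transcript_id, flavor) {
  exon_len <- c(36L, 45L + sample(0:9, 1L) * 3L, 90L + sample(0:9, 1L) * 3L,
                75L + sample(0:9, 1L) * 3L)
  # cds offset inside exon 1, phased so that exon 2 starts mid-codon for
  # "start_hit" ((E2 - cds_start) %% 3 == 1) and in-frame otherwise
  u <- 12L
  if (flavor == "start_hit") {
    off <- (exon_len[1] + exon_len[2] - u) %% 3L
    u <- u + ((off - 1L) %% 3L)
  } else {
    u <- u + ((exon_len[1] + exon_len[2] - u) %% 3L)
  }
  cds_start <- exon_len[1] + u
  intron_len <- c(24L, 24L, 24L)
  if (flavor == "upstream") {
    # retained 5'UTR intron must keep the downstream CDS in frame with its
    # internal ATG at offset 3: (cds_start + ilen0 - exon_len[1] - 6) % 3 == 0
    intron_len[1] <- 30L
    intron_len[1] <- intron_len[1] +
      ((exon_len[1] + 6L - cds_start - intron_len[1]) %% 3L)
  }
  if (flavor == "start_hit") {
    # retained CDS intron: internal ATG at offset 3 must read into exon 2 in
    # the reference frame: (ilen - 3) %% 3 == (E2 - cds_start) %% 3 == 1
    intron_len[2] <- 30L + ((1L - (30L - 3L)) %% 3L)
  }
  exons <- vapply(exon_len, function(n) scrub_atg(random_nt(n, 0.5)),
                  character(1))
  introns <- vapply(intron_len, function(n) scrub_atg(random_nt(n, 0.5)),
                    character(1))
  t <- finish_gene(transcript_id, exons, introns, cds_start = cds_start)

  if (flavor == "downstream") {
    # restart ATG at exon-2 offset 1: one off the reference frame, so the
    # skipped-start variant initiates downstream of the junction and encodes
    # a novel product (its N-terminal peptide cannot coincide with any
    # reference substring). Stops and K/R are recoded in the restart frame
    # through exon 2, and a stop codon is placed mid-exon 3 in that frame.
    e2 <- t$exons[3]
    substr(e2, 2L, 4L) <- "ATG"
    e2 <- scrub_codons(e2, frame_from = 4L, also_kr = TRUE, repl = "CCC")
    t$exons[3] <- e2
    e3 <- t$exons[4]
    ph <- (3L - ((nchar(e2) - 4L) %% 3L)) %% 3L   # restart frame entering exon 3
    mid <- ph + 3L * (((nchar(e3) %/% 2L) - ph) %/% 3L)
    e3 <- scrub_codons(e3, frame_from = ph, to = mid, repl = "CCC")
    substr(e3, mid + 1L, mid + 3L) <- "TAA"
    t$exons[4] <- e3
  } else if (flavor == "start_hit") {
    intr <- t$introns[2]
    substr(intr, 4L, 6L) <- "ATG"
    # stop in the reference reading frame early in the retained intron
    o <- 6L + ((2L - 6L) %% 3L)                  # first o >= 6 with o %% 3 == 2
    substr(intr, o + 1L, o + 3L) <- "TAA"
    intr <- scrub_intron_frame(intr, from = 6L, keep = c(o, o + 1L, o + 2L))
    t$introns[2] <- intr
  } else {                                       # upstream
    intr <- t$introns[1]
    substr(intr, 4L, 6L) <- "ATG"
    intr <- scrub_intron_frame(intr, from = 6L, keep = integer(0))
    t$introns[1] <- intr
    # also recode stops/K/R in the 5'UTR stretch of exon 1 that the extended
    # protein reads through (frame of cds_start)
    e1 <- t$exons[2]
    ph <- t$cds_start - nchar(t$exons[1])        # UTR length within exon 1
    p <- ph %% 3L                                # codon phase entering exon 1
    e1 <- scrub_codons(e1, frame_from = p, to = ph, also_kr = TRUE)
    t$exons[2] <- e1
  }
  transcript(t$transcript_id, t$exons, t$introns, cds_start = t$cds_start,
             cds_end = t$cds_end)
}

# Recode stop and K/R codons in the ATG frame of an engineered intron
# (codon starts at offsets 6, 9, ... 0-based), leaving `keep` positions
# untouched.
scrub_intron_frame <- function(intr, from, keep) {
  p <- from
  bad <- c(STOP_CODONS, "AAA", "AAG", "AGA", "AGG", "CGA", "CGC", "CGG", "CGT")
  while (p + 3L <= nchar(intr)) {
    span <- p:(p + 2L)
    cod <- substr(intr, p + 1L, p + 3L)
    if (cod %in% bad) {
      free <- !(span %in% keep)
      repl <- strsplit("CCT", "")[[1]]
      cur <- strsplit(cod, "")[[1]]
      cur[free] <- repl[free]
      substr(intr, p + 1L, p + 3L) <- paste(cur, collapse = "")
    }
    p <- p + 3L
  }
  intr
}

# The event paired with a TIS-engineered gene.
tis_event <- function(t, flavor, event_id, support) {
  switch(flavor,
    downstream = splice_event(event_id, t$transcript_id, "EXON_SKIP",
                              list(skip_from = 1L, skip_to = 1L), support),
    start_hit = splice_event(event_id, t$transcript_id, "INTRON_RETAIN",
                             list(intron = 1L), support),
    upstream = splice_event(event_id, t$transcript_id, "INTRON_RETAIN",
                            list(intron = 0L), support))
}

# ---- Whole-study generation -------------------------------------------------

#' Generate a complete synthetic study with ground truth
#'
#' Generates `n_genes` toy genes with one event each, the matching reference
#' proteome (annotated-CDS translations under `ref|<accession>` headers),
#' and a per-event truth table computed by the independent oracle: expected
#' variant protein, expected variant-unique peptides (against the whole
#' fixture reference proteome, mirroring the two-stage uniqueness
#' definition), expected recovery, and expected TIS classification.
#'
#' The `default` preset samples event types at transcriptome-like
#' proportions with roughly half combined events; the `tis-rich` preset
#' engineers every gene/event pair to disturb the translation start so all
#' three alternative-TIS categories occur in force.
#'
#' @param seed integer seed.
#' @param n_genes number of genes (one event per gene).
#' @param preset `"default"` or `"tis-rich"`.
#' @param config an [sp_config()].
#' @return list with `transcripts`, `events`, `reference_proteome` (named
#'   character vector), and `truth` (data frame).
#' @export
generate_fixture_set <- function(seed, n_genes = 200L,
                                 preset = c("default", "tis-rich"),
                                 config = sp_config()) {
  preset <- match.arg(preset)
  transcripts <- vector("list", n_genes)
  events <- vector("list", n_genes)
  flavors <- c("downstream", "start_hit", "upstream")
  for (i in seq_len(n_genes)) {
    tid <- sprintf("TX%04d", i)
    eid <- sprintf("EV%05d", i)
    gs <- derive_seed(seed, i)
    if (preset == "tis-rich") {
      fl <- flavors[(i - 1L) %% 3L + 1L]
      with_seed(gs, {
        transcripts[[i]] <- tis_gene(tid, fl)
        events[[i]] <- tis_event(transcripts[[i]], fl, eid,
                                 support = sample(2:50, 1L))
      })
    } else {
      transcripts[[i]] <- generate_gene(gs, transcript_id = tid)
      ev <- suppressWarnings(
        generate_events(transcripts[[i]], n = 1L,
                        mix = c(EXON_SKIP = 18, ALT_3SS = 15,
                                ALT_5SS = 13, INTRON_RETAIN = 6,
                                COMBINED = 48),
                        seed = derive_seed(gs, 7L), id_prefix = "ZZ"))
      if (!length(ev)) next
      e <- ev[[1]]
      e$event_id <- eid
      if (inherits(e, "combined_event")) {
        for (k in seq_along(e$events)) {
          e$events[[k]]$event_id <- sprintf("%s.%d", eid, k)
        }
      }
      events[[i]] <- e
    }
  }
  keep <- !vapply(events, is.null, logical(1))
  transcripts <- transcripts[keep]
  events <- events[keep]
  names(transcripts) <- vapply(transcripts, `[[`, character(1),
                               "transcript_id")

  reference_proteome <- vapply(transcripts, reference_protein_oracle,
                               character(1))
  names(reference_proteome) <- sprintf("ref|%s reference product",
                                       names(transcripts))
  truth <- fixture_truth(transcripts, events, reference_proteome, config)
  list(transcripts = transcripts, events = events,
       reference_proteome = reference_proteome, truth = truth,
       seed = seed, preset = preset)
}

# Annotated-CDS translation by the oracle's codon loop.
reference_protein_oracle <- function(t) {
  cds <- substr(paste(t$exons, collapse = ""), t$cds_start + 1L,
                t$cds_end - 3L)
  oracle_translate(cds, 0L, nchar(cds))
}

# Truth table over a fixture set, via the oracle only (event application,
# ORF finding, translation, digestion); classification reuses the rule
# functions on oracle-built objects.
fixture_truth <- function(transcripts, events, reference_proteome, config) {
  # oracle reference tryptic universe
  ref_universe <- new.env(parent = emptyenv())
  for (k in seq_along(reference_proteome)) {
    dg <- oracle_digest(reference_proteome[[k]],
                        max_missed = config$max_missed,
                        min_length = config$min_length)
    for (s in unique(dg$sequence)) ref_universe[[s]] <- TRUE
  }

  rows <- vector("list", length(events))
  proteins <- character(length(events))
  for (k in seq_along(events)) {
    e <- events[[k]]
    t <- transcripts[[e$transcript_id]]
    vp <- oracle_variant_protein(t, e)
    code <- event_code(e, config)
    if (is.null(vp)) {
      rows[[k]] <- data.frame(
        event_id = e$event_id, transcript_id = t$transcript_id,
        event_type = code, protein = NA_character_, dedup_into = NA_character_,
        unique_peptides = "", expect_recovered = FALSE, is_tis = NA,
        tis_category = NA_character_, first_atg_downstream = NA,
        wilson_model = NA, orf_disrupting = NA)
      next
    }
    proteins[k] <- vp$sequence
    dg <- oracle_digest(vp$sequence, max_missed = config$max_missed,
                        min_length = config$min_length)
    uniq <- dg[!vapply(dg$sequence, function(s) {
      isTRUE(ref_universe[[s]])
    }, logical(1)) & !vapply(dg$sequence, grepl, logical(1),
                             x = vp$reference_protein, fixed = TRUE,
                             USE.NAMES = FALSE), , drop = FALSE]
    upep <- unique(uniq$sequence)
    is_tis <- FALSE
    if (length(upep)) {
      is_tis <- any(vapply(upep, function(s) {
        st <- min(dg$start[dg$sequence == s])
        st == 1L || (st == 2L && substr(vp$sequence, 1L, 1L) == "M")
      }, logical(1)))
    }
    tis <- if (is_tis) classify_tis(vp, config) else
      list(tis_category = NA_character_, first_atg_downstream = NA,
           wilson_model = NA, orf_disrupting = NA)
    rows[[k]] <- data.frame(
      event_id = e$event_id, transcript_id = t$transcript_id,
      event_type = code, protein = vp$sequence, dedup_into = NA_character_,
      unique_peptides = paste(sort(upep), collapse = ";"),
      expect_recovered = length(upep) > 0L,
      is_tis = if (length(upep)) is_tis else NA,
      tis_category = tis$tis_category,
      first_atg_downstream = tis$first_atg_downstream,
      wilson_model = tis$wilson_model,
      orf_disrupting = tis$orf_disrupting)
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL

  # exact-duplicate proteins: only the lexicographically first event id
  # survives database construction
  has_prot <- !is.na(truth$protein)
  o <- order(truth$event_id, method = "radix")
  seen <- new.env(parent = emptyenv())
  for (k in o) {
    if (!has_prot[k]) next
    key <- truth$protein[k]
    first <- seen[[key]]
    if (is.null(first)) {
      seen[[key]] <- truth$event_id[k]
    } else {
      truth$dedup_into[k] <- first
      truth$expect_recovered[k] <- FALSE
    }
  }
  truth
}

# ---- Observation simulation -------------------------------------------------

#' Simulate an identified-peptide table from a database
#'
#' Emits each distinct tryptic peptide of the database with probability
#' `detect_prob`, with accession lists computed honestly from the database
#' (every entry whose digest contains the peptide), log-normal intensities
#' (median 1e7, sigma one log10 unit) and bounded scores. Decoy rows carry
#' reversed sequences and a `+` Reverse flag; contaminant rows a `+`
#' Potential contaminant flag. Deterministic under `seed`.
#'
#' @param db a `variant_db`.
#' @param detect_prob per-peptide detection probability in `[0, 1]`.
#' @param n_decoy_rows,n_contaminant_rows rows to add with decoy /
#'   contaminant flags.
#' @param seed integer seed.
#' @return data frame in the `peptides.txt` dialect (`Sequence`, `Proteins`,
#'   `Score`, `Intensity`, `Reverse`, `Potential contaminant`).
#' @export
simulate_observed_peptides <- function(db, detect_prob = 1,
                                       n_decoy_rows = 0L,
                                       n_contaminant_rows = 0L, seed = 1L) {
  stopifnot(inherits(db, "variant_db"))
  cfg <- db$config
  pep_acc <- new.env(parent = emptyenv())
  headers <- names(db$sequences)
  for (k in seq_along(db$sequences)) {
    dg <- digest(db$sequences[[k]], max_missed = cfg$max_missed,
                 min_length = cfg$min_length,
                 nterm_met = cfg$nterm_met_cleavage)
    for (s in unique(dg$sequence)) {
      pep_acc[[s]] <- c(pep_acc[[s]], headers[k])
    }
  }
  all_pep <- sort(ls(pep_acc))
  with_seed(seed, {
    det <- stats::runif(length(all_pep)) < detect_prob
    kept <- all_pep[det]
    n <- length(kept)
    rows <- data.frame(
      Sequence = kept,
      Proteins = vapply(kept, function(s) {
        paste(pep_acc[[s]], collapse = ";")
      }, character(1), USE.NAMES = FALSE),
      Score = round(stats::runif(n, 30, 300), 2),
      Intensity = signif(10^stats::rnorm(n, mean = 7, sd = 1), 4),
      Reverse = rep("", n),
      `Potential contaminant` = rep("", n),
      check.names = FALSE)
    extra <- function(m, col) {
      if (!m) return(NULL)
      src <- if (length(kept)) sample(kept, m, replace = TRUE) else
        vapply(seq_len(m), function(i) {
          paste(sample(c("A", "G", "S", "T", "L", "V"), 9, replace = TRUE),
                collapse = "")
        }, character(1))
      seqs <- vapply(strsplit(src, ""), function(x) {
        paste(rev(x), collapse = "")
      }, character(1))
      data.frame(Sequence = seqs, Proteins = rep("", m),
                 Score = round(stats::runif(m, 30, 300), 2),
                 Intensity = signif(10^stats::rnorm(m, 7, 1), 4),
                 Reverse = if (col == "Reverse") rep("+", m) else rep("", m),
                 `Potential contaminant` = if (col == "contaminant") {
                   rep("+", m)
                 } else rep("", m),
                 check.names = FALSE)
    }
    out <- rbind(rows, extra(as.integer(n_decoy_rows), "Reverse"),
                 extra(as.integer(n_contaminant_rows), "contaminant"))
    rownames(out) <- NULL
    out
  })
}
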