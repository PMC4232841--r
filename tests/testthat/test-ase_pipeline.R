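make_id_table <- function(rows) {
  do.call(rbind, lapply(rows, function(r) {
    data.frame(Sequence = r$seq, Proteins = r$prot %||% "",
               Score = r$score %||% 100, Intensity = r$int %||% 1e7,
               Reverse = r$rev %||% "", `Potential contaminant` = r$con %||% "",
               check.names = FALSE)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identification parsing strips decoy and contaminant rows", {
  tab <- make_id_table(list(
    list(seq = "AAAAAAK"), list(seq = "CCCCCCK"),
    list(seq = "DDDDDDK", rev = "+"),
    list(seq = "EEEEEEK", con = "+"),
    list(seq = "FFFFFFK")))
  out <- parse_identifications(tab)
  expect_identical(out$sequence, c("AAAAAAK", "CCCCCCK", "FFFFFFK"))
  expect_identical(attr(out, "n_removed_reverse"), 1L)
  expect_identical(attr(out, "n_removed_contaminant"), 1L)

  # file round trip with the same dialect
  path <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out2 <- parse_identifications(path, source_engine = "denovo")
  expect_identical(out2$sequence, out$sequence)
  expect_identical(unique(out2$source_engine), "denovo")

  expect_identical(nrow(parse_identifications(tab[0, ])), 0L)
  # bare single-column list parses with absent metadata
  bare <- data.frame(Sequence = c("GGGGGGK"))
  out3 <- parse_identifications(bare)
  expect_true(is.na(out3$proteins))
  expect_true(is.na(out3$score))
  expect_error(parse_identifications(data.frame(Peptide = "AAAK")),
               "Sequence column")
})

test_that("N-terminal peptide detection honours Met-removal", {
  expect_true(detect_nterminal(1, "MAAEEFFK"))
  expect_true(detect_nterminal(2, "MAAEEFFK"))
  expect_false(detect_nterminal(2, "MAAEEFFK", nterm_met_cleavage = FALSE))
  expect_false(detect_nterminal(2, "XAAEEFFK"))
  expect_false(detect_nterminal(5, "MAAEEFFK"))
  expect_true(detect_nterminal(data.frame(start = 1), list(sequence = "MK")))
})

test_that("two-stage support calling matches the worked uniqueness example", {
  toy <- uniqueness_toy()
  ref_prot <- predict_variant_protein(toy$transcript, toy$event)$reference_protein
  ref <- c("ref|NM_TOY1 template" = ref_prot)
  db <- build_database(toy$transcript, list(toy$event), ref)
  idx <- build_peptide_index(ref)

  obs <- simulate_observed_peptides(db, detect_prob = 1, seed = 3)
  rec <- call_ase_support(parse_identifications(obs), db, idx)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$event_id, "SP001")
  expect_identical(rec$event_type, "ES")
  expect_identical(sort(strsplit(rec$peptides, ";")[[1]]),
                   c("MAAKGGHHIIK", "MAAKGGHHIIKLLMMNNR"))
  expect_true(rec$is_tis)
  # an in-frame skip leaving identical C-termini is the amino-terminal
  # isoform (Wilson) configuration
  expect_true(rec$wilson_model)
  expect_false(rec$orf_disrupting)

  # stage-1 precedence: a peptide listed with a reference accession is
  # rejected even though its sequence is variant-unique
  tainted <- data.frame(
    Sequence = "MAAKGGHHIIK",
    Proteins = "NM_TOY1# (ES:SP001);ref|NM_TOY1 template",
    check.names = FALSE)
  rec2 <- call_ase_support(parse_identifications(tainted), db, idx)
  expect_identical(nrow(rec2), 0L)

  # a shared (non-unique) peptide never supports an event
  shared <- data.frame(Sequence = "GGHHIIK", check.names = FALSE)
  expect_identical(nrow(call_ase_support(parse_identifications(shared),
                                         db, idx)), 0L)

  # peptides locating nowhere in the database are reported, not errors
  lost <- data.frame(Sequence = "WWWWWWWK", check.names = FALSE)
  rec3 <- call_ase_support(parse_identifications(lost), db, idx)
  expect_identical(attr(rec3, "unmatched_peptides"), "WWWWWWWK")
})

test_that("TIS classification separates downstream, start-affected, upstream", {
  # construct one engineered gene of each flavor and classify its variant
  set.seed(1234)
  for (want in c(A = "downstream", B = "start_hit", C = "upstream")) {
    t <- spliceptide:::tis_gene("TXC", want)
    e <- spliceptide:::tis_event(t, want, "EVC", 2L)
    vp <- predict_variant_protein(t, e)
    got <- classify_tis(vp)
    expect_identical(got$tis_category, names(which(c(
      A = "downstream", B = "start_hit", C = "upstream") == want)))
  }

  # intron retention that destroys the reference start: category B with a
  # disrupted ORF (hand-checked coordinates)
  t <- transcript("TB", c("CCCATGAAACCC", "AAATAAGGGTGA"), c("GGATGCCCCCACCACCA"),
                  cds_start = 3, cds_end = 18)
  vp <- predict_variant_protein(t, splice_event("EB", "TB", "INTRON_RETAIN",
                                                list(intron = 0)))
  # largest ORF initiates at the ATG inside the retained intron
  expect_identical(vp$tis_mrna_offset, 14L)
  cls <- classify_tis(vp)
  expect_identical(cls$tis_category, "B")
  expect_true(cls$orf_disrupting)
  expect_false(cls$wilson_model)

  expect_error(classify_tis(list(sequence = "MK", coord_map = NULL)),
               "coordinate map")
})

test_that("every TIS record gets exactly one category and coherent flags", {
  fx <- generate_fixture_set(seed = 21, n_genes = 24, preset = "tis-rich")
  db <- build_database(fx$transcripts, fx$events, fx$reference_proteome)
  idx <- build_peptide_index(fx$reference_proteome)
  rec <- call_ase_support(parse_identifications(
    simulate_observed_peptides(db, detect_prob = 1, seed = 5)), db, idx)
  tis <- rec[rec$is_tis, ]
  expect_true(nrow(tis) > 0)
  expect_true(all(tis$tis_category %in% c("A", "B", "C")))
  both <- !is.na(tis$wilson_model) & !is.na(tis$orf_disrupting)
  expect_true(all(tis$wilson_model[both] != tis$orf_disrupting[both]))
})

test_that("merging result sets is a union with inclusion-exclusion", {
  mk <- function(ids, engine) data.frame(
    event_id = ids, event_type = "ES", n_peptides = 1L,
    peptides = paste0("PEP", ids), is_tis = FALSE,
    tis_category = NA_character_, first_atg_downstream = NA,
    wilson_model = NA, orf_disrupting = NA, source_engines = engine,
    best_score = 10, max_intensity = 1e6,
    shared_variant_peptides = "")
  # the published set algebra: 808 probabilistic + 218 de novo sharing 134
  a <- mk(sprintf("E%04d", 1:808), "probabilistic")
  b <- mk(sprintf("E%04d", 675:892), "denovo")
  m <- merge_result_sets(a, b)
  s <- attr(m, "summary")
  expect_identical(s$n_a, 808L)
  expect_identical(s$n_b, 218L)
  expect_identical(s$n_overlap, 134L)
  expect_identical(s$n_union, 892L)
  expect_identical(s$n_union, s$n_a + s$n_b - s$n_overlap)
  # overlapping records union their engines
  e700 <- m[m$event_id == "E0700", ]
  expect_identical(e700$source_engines, "denovo;probabilistic")

  # disjoint sets add; identical sets are idempotent
  d <- merge_result_sets(mk("X1", "p"), mk("X2", "d"))
  expect_identical(attr(d, "summary")$n_union, 2L)
  same <- merge_result_sets(a, a)
  expect_identical(attr(same, "summary")$n_union, 808L)

  # conflicting event types refuse to merge
  b2 <- mk("E0001", "denovo")
  b2$event_type <- "IR"
  expect_error(merge_result_sets(a, b2), "conflicting event_type")
})

test_that("frequency tables use round-half-up percentages over simple events", {
  codes <- c(rep("ES", 182), rep("A3SS", 130), rep("A5SS", 90),
             rep("IR", 61), rep("CASE", 429))
  ft <- event_frequency_table(codes)
  expect_identical(ft$n_simple, 463L)
  expect_identical(ft$n_complex, 429L)
  tab <- stats::setNames(ft$simple$percent, ft$simple$event_type)
  expect_identical(tab[["ES"]], 39L)    # 182/463 = 39.3
  expect_identical(tab[["A3SS"]], 28L)  # 130/463 = 28.08
  expect_identical(tab[["IR"]], 13L)    # 61/463 = 13.2
  expect_identical(tab[["DS"]], 0L)
  expect_true(abs(sum(ft$simple$percent) - 100) <= 2)

  single <- event_frequency_table(rep("IR", 5))
  expect_identical(single$simple$percent[single$simple$event_type == "IR"],
                   100L)
  empty <- event_frequency_table(character(0))
  expect_identical(empty$n_simple, 0L)
  expect_true(all(is.na(empty$simple$percent)))
})

test_that("event records survive a TSV round trip", {
  toy <- uniqueness_toy()
  ref <- c("ref|NM_TOY1 template" = predict_variant_protein(
    toy$transcript, toy$event)$reference_protein)
  db <- build_database(toy$transcript, list(toy$event), ref)
  idx <- build_peptide_index(ref)
  rec <- call_ase_support(parse_identifications(
    simulate_observed_peptides(db, detect_prob = 1, seed = 3)), db, idx)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ase_tsv(rec, path)
  back <- read_ase_tsv(path)
  expect_identical(back$event_id, rec$event_id)
  expect_identical(back$peptides, rec$peptides)
  expect_identical(back$is_tis, rec$is_tis)
})
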