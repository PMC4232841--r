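test_that("variant proteins compose splice, ORF and translation stages", {
  t <- transcript("T1", c("ATGGCA", "GAATTC", "TAA"), c("GT", "AG"),
                  cds_start = 0, cds_end = 15)
  e <- splice_event("E1", "T1", "EXON_SKIP", list(skip_from = 1, skip_to = 1))
  vp <- predict_variant_protein(t, e)
  expect_identical(vp$sequence, "MA")
  expect_identical(vp$reference_protein, "MAEF")
  expect_identical(encode_header(vp$tag), "T1# (ES:E1)")
  expect_identical(vp$tis_mrna_offset, 0L)

  # in-frame intron retention inserts a residue
  t2 <- transcript("T2", c("ATGAAA", "TAA"), c("GGG"), cds_start = 0,
                   cds_end = 9)
  vp2 <- predict_variant_protein(t2, splice_event("E2", "T2", "INTRON_RETAIN",
                                                  list(intron = 0)))
  expect_identical(vp2$sequence, "MKG")
  expect_identical(vp2$reference_protein, "MK")

  # an event leaving the product unchanged is filtered out: skipping an
  # exon that is entirely 3' UTR
  t3 <- transcript("T3", c("ATGAAATAA", "CCCCCC", "GGGGGG"),
                   c("GTG", "GTA"), cds_start = 0, cds_end = 9)
  expect_null(predict_variant_protein(t3, splice_event("E3", "T3",
    "EXON_SKIP", list(skip_from = 2, skip_to = 2))))
  # and a variant with no ATG at all yields nothing
  t4 <- transcript("T4", c("ATGAAA", "CCCTAA"), c("GTAG"), cds_start = 0,
                   cds_end = 12)
  expect_null(predict_variant_protein(t4, splice_event("E4", "T4",
    "ALT_5SS", list(exon = 0, shift = -5))))
  expect_error(predict_variant_protein(
    transcript("T5", c("ATGAAA", "TAA"), c("GGG")),
    splice_event("E5", "T5", "INTRON_RETAIN", list(intron = 0))),
    "no annotated CDS")
})

test_that("database construction filters, de-duplicates, tags, and reports", {
  t <- transcript("T1", c("ATGGCA", "GAATTC", "TAA"), c("GT", "AG"),
                  cds_start = 0, cds_end = 15)
  # E1 and E9 describe the same skip under different ids (identical
  # product, so E9 de-duplicates into E1); E2 is under-supported
  events <- list(
    splice_event("E1", "T1", "EXON_SKIP", list(skip_from = 1, skip_to = 1),
                 support_count = 3),
    splice_event("E9", "T1", "EXON_SKIP", list(skip_from = 1, skip_to = 1),
                 support_count = 3),
    splice_event("E2", "T1", "INTRON_RETAIN", list(intron = 0),
                 support_count = 1))
  ref <- c("sp|P1|TOY a reference protein" = "MAEFWWWW")
  db <- build_database(t, events, ref)
  rep <- stats::setNames(db$report$count, db$report$stage)
  expect_equal(rep[["events_in"]], 3)
  expect_equal(rep[["below_support"]], 1)
  expect_equal(rep[["deduplicated"]], 1)
  expect_equal(rep[["variants_kept"]], 1)
  expect_equal(rep[["total_entries"]],
               rep[["variants_kept"]] + rep[["reference_entries"]])
  # conservation over all drop reasons
  expect_equal(rep[["events_in"]],
               rep[["below_support"]] + rep[["no_orf"]] +
               rep[["identical_product"]] + rep[["deduplicated"]] +
               rep[["variants_kept"]])
  # duplicate group recorded: E9's product equals E1's, E1 kept
  expect_identical(db$duplicates, list(E1 = "E9"))
  # reference headers preserved verbatim, after the variants
  expect_identical(db$headers,
                   c("T1# (ES:E1)", "sp|P1|TOY a reference protein"))
  for (v in db$variants) {
    expect_true(decode_header(encode_header(v$tag))$is_variant)
    expect_false(identical(v$sequence, v$reference_protein))
  }

  expect_error(build_database(t, list(events[[1]], events[[1]]), ref),
               "duplicate event ids")
  orphan <- splice_event("EX", "NOPE", "INTRON_RETAIN", list(intron = 0))
  expect_error(build_database(t, list(orphan), ref), "unknown transcripts")
})

test_that("database FASTA output is byte-identical across runs", {
  toy <- uniqueness_toy()
  ref <- c("ref|NM_TOY1 reference" = predict_variant_protein(
    toy$transcript, toy$event)$reference_protein)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_db_fasta(build_database(toy$transcript, list(toy$event), ref), f1)
  write_db_fasta(build_database(toy$transcript, list(toy$event), ref), f2)
  expect_identical(readLines(f1), readLines(f2))
  # wrapped at 60 columns, uppercase
  lines <- readLines(f1)
  expect_true(all(nchar(lines) <= 60))
  expect_false(any(grepl("[a-z]", lines[!startsWith(lines, ">")])))
  # and the FASTA reads back with full descriptions as names
  back <- read_proteome_fasta(f1)
  expect_identical(names(back)[1], "NM_TOY1# (ES:SP001)")
})

test_that("no two variant records share a sequence", {
  set.seed(31)
  fx <- generate_fixture_set(seed = 13, n_genes = 25, preset = "default")
  db <- build_database(fx$transcripts, fx$events, fx$reference_proteome)
  seqs <- vapply(db$variants, `[[`, character(1), "sequence")
  expect_identical(anyDuplicated(seqs), 0L)
})
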