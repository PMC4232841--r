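test_that("header tag codec encodes the published rule and round-trips", {
  tag <- header_tag("NM_000546", "ES", "SP00123")
  expect_identical(encode_header(tag), "NM_000546# (ES:SP00123)")
  d <- decode_header(encode_header(tag))
  expect_true(d$is_variant)
  expect_identical(d$tag, tag)

  # round-trip property over random delimiter-free fields
  set.seed(101)
  alphabet <- c(LETTERS, letters, 0:9, "_", ".", "-", "|")
  for (i in 1:100) {
    f <- vapply(1:3, function(j) {
      paste(sample(alphabet, sample(1:12, 1), replace = TRUE), collapse = "")
    }, character(1))
    tg <- header_tag(f[1], f[2], f[3])
    expect_identical(decode_header(encode_header(tg))$tag, tg)
  }
})

test_that("decode_header passes reference headers through and flags malformed ones", {
  d <- decode_header(">sp|P04637|P53_HUMAN Cellular tumor antigen p53")
  expect_false(d$is_variant)
  expect_identical(d$accession, "sp|P04637|P53_HUMAN Cellular tumor antigen p53")
  expect_error(decode_header("NM_1# (ES"), "malformed")
  expect_error(header_tag("NM#1", "ES", "SP1"), "delimiter")
  expect_error(header_tag("", "ES", "SP1"), "non-empty")
})

test_that("decode accepts zero or more spaces after the hash", {
  for (h in c("NM_1#(ES:SP1)", "NM_1# (ES:SP1)", "NM_1#   (ES:SP1)")) {
    d <- decode_header(h)
    expect_true(d$is_variant)
    expect_identical(d$tag$splooce_id, "SP1")
  }
})

test_that("transcript construction enforces its invariants", {
  expect_error(transcript("T", c("ATG", "TAA"), character(0)), "introns")
  expect_error(transcript("T", c("ATGU"), character(0)), "A,C,G,T,N")
  expect_error(transcript("T", c("ATGAAAAAA"), character(0),
                          cds_start = 0, cds_end = 7), "divisible")
  expect_error(transcript("T", c("ATGAAA"), character(0),
                          cds_start = 0, cds_end = 9), "out of bounds")
  t <- transcript("T", c("ATGAAA", "TAA"), c("GGG"), cds_start = 0,
                  cds_end = 9)
  expect_s3_class(t, "transcript")
})

test_that("validate_event reports violations as data, not conditions", {
  t <- transcript("T1", c("ATGGCA", "GAATTC", "TAA"), c("GT", "AG"))
  ok <- splice_event("E1", "T1", "EXON_SKIP",
                     list(skip_from = 1, skip_to = 1))
  expect_identical(validate_event(t, ok), character(0))

  bad_ir <- splice_event("E2", "T1", "INTRON_RETAIN", list(intron = 2))
  v <- validate_event(t, bad_ir)
  expect_length(v, 1)
  expect_match(v, "out of bounds")

  # ALT_3SS is undefined for exon 0; shifts must stay within flanks
  expect_match(validate_event(t, splice_event("E3", "T1", "ALT_3SS",
    list(exon = 0, shift = -1)))[1], "exon 0")
  expect_match(validate_event(t, splice_event("E4", "T1", "ALT_3SS",
    list(exon = 1, shift = -5)))[1], "exceeds")
  expect_match(validate_event(t, splice_event("E5", "T1", "ALT_5SS",
    list(exon = 2, shift = 1)))[1], "last exon")

  # events targeting the wrong transcript are violations too
  expect_match(validate_event(t, splice_event("E6", "OTHER", "EXON_SKIP",
    list(skip_from = 0, skip_to = 0)))[1], "targets transcript")
})

test_that("combined events reject overlapping constituents, allow adjacency", {
  t <- transcript("T1", c("ATGGCA", "GAATTC", "CCAGTT", "TAA"),
                  c("GTAAG", "GTCAG", "GTTAG"))
  # two events claiming exon 1's acceptor region collide
  clash <- combined_event("C1", list(
    splice_event("a", "T1", "ALT_3SS", list(exon = 1, shift = -2)),
    splice_event("b", "T1", "EXON_SKIP", list(skip_from = 1, skip_to = 1))))
  expect_match(paste(validate_event(t, clash), collapse = " "), "overlapping")

  adjacent <- combined_event("C2", list(
    splice_event("a", "T1", "EXON_SKIP", list(skip_from = 1, skip_to = 1)),
    splice_event("b", "T1", "EXON_SKIP", list(skip_from = 2, skip_to = 2))))
  expect_identical(validate_event(t, adjacent), character(0))

  compatible <- combined_event("C3", list(
    splice_event("a", "T1", "EXON_SKIP", list(skip_from = 1, skip_to = 1)),
    splice_event("b", "T1", "INTRON_RETAIN", list(intron = 2))))
  expect_identical(validate_event(t, compatible), character(0))
})

test_that("validate_event is total over random well-typed input", {
  set.seed(77)
  for (i in 1:100) {
    t <- make_toy_transcript()
    type <- sample(c("EXON_SKIP", "ALT_3SS", "ALT_5SS", "INTRON_RETAIN"), 1)
    params <- switch(type,
      EXON_SKIP = {
        a <- sample(-1:9, 1)
        list(skip_from = a, skip_to = a + sample(0:9, 1))
      },
      ALT_3SS = ,
      ALT_5SS = list(exon = sample(-1:9, 1), shift = sample(-80:80, 1)),
      INTRON_RETAIN = list(intron = sample(-1:9, 1)))
    e <- tryCatch(splice_event("X", "TOY", type, params),
                  error = function(c) NULL)
    if (is.null(e)) next  # constructor-level rejection is fine
    expect_no_error(validate_event(t, e))
  }
})

test_that("event TSV round-trips simple and combined events", {
  t <- transcript("T1", c("ATGGCA", "GAATTC", "CCAGTT", "TAA"),
                  c("GTAAG", "GTCAG", "GTTAG"))
  events <- list(
    splice_event("E1", "T1", "EXON_SKIP", list(skip_from = 1, skip_to = 2),
                 support_count = 5),
    splice_event("E2", "T1", "ALT_3SS", list(exon = 2, shift = -3)),
    splice_event("E3", "T1", "ALT_5SS", list(exon = 0, shift = 4)),
    splice_event("E4", "T1", "INTRON_RETAIN", list(intron = 0)),
    combined_event("E5", list(
      splice_event("E5.1", "T1", "EXON_SKIP", list(skip_from = 1, skip_to = 1)),
      splice_event("E5.2", "T1", "INTRON_RETAIN", list(intron = 2))),
      support_count = 7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(events, path)
  back <- read_events_tsv(path)
  expect_length(back, 5)
  for (k in seq_along(events)) {
    expect_identical(class(back[[k]]), class(events[[k]]))
    expect_identical(back[[k]]$event_id, events[[k]]$event_id)
    expect_identical(back[[k]]$support_count, events[[k]]$support_count)
  }
  expect_identical(back[[1]]$params, list(skip_from = 1L, skip_to = 2L))
  expect_identical(back[[2]]$params, list(exon = 2L, shift = -3L))
  expect_identical(back[[5]]$events[[1]]$event_type, "EXON_SKIP")
  expect_identical(back[[5]]$events[[2]]$params$intron, 2L)
  for (e in back) expect_identical(validate_event(t, e), character(0))
})

test_that("transcript TSV/FASTA pair round-trips", {
  set.seed(5)
  t1 <- make_toy_transcript(n_exons = 3, id = "TXA")
  t2 <- transcript("TXB", c("ATGAAA", "TAA"), c("GGG"), cds_start = 0,
                   cds_end = 9, gene_id = "GENEB")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_transcripts(list(t1, t2), tsv, fa)
  back <- read_transcripts(tsv, fa)
  expect_identical(back$TXA$exons, t1$exons)
  expect_identical(back$TXA$introns, t1$introns)
  expect_true(is.na(back$TXA$cds_start))
  expect_identical(back$TXB$cds_start, 0L)
  expect_identical(back$TXB$cds_end, 9L)
  expect_identical(back$TXB$gene_id, "GENEB")
})

test_that("configuration validates codes and reads YAML", {
  cfg <- sp_config(min_support = 3, il_equivalence = TRUE)
  expect_identical(cfg$min_support, 3L)
  expect_true(cfg$il_equivalence)
  expect_error(sp_config(event_codes = c(EXON_SKIP = "E#S")), "delimiter|#")

  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("min_support: 4", "allow_open_ended: true",
               "event_codes:", "  EXON_SKIP: SKIP"), y)
  cfg2 <- read_config(y)
  expect_identical(cfg2$min_support, 4L)
  expect_true(cfg2$allow_open_ended)
  expect_identical(unname(cfg2$event_codes[["EXON_SKIP"]]), "SKIP")
  writeLines("bogus_key: 1", y)
  expect_error(read_config(y), "unknown configuration")
})
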