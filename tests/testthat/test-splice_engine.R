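test_that("splice_reference concatenates exons", {
  t <- transcript("T1", c("ATGGCA", "GAATTC", "TAA"), c("GT", "AG"))
  expect_identical(splice_reference(t), "ATGGCAGAATTCTAA")
  expect_identical(splice_reference(transcript("T2", "ATG")), "ATG")
  set.seed(2)
  for (i in 1:20) {
    tt <- make_toy_transcript()
    expect_identical(nchar(splice_reference(tt)), sum(nchar(tt$exons)))
  }
})

test_that("apply_event performs each edit type on the block structure", {
  t <- transcript("T1", c("ATGGCA", "GAATTC", "TAA"), c("GT", "AG"))
  v <- apply_event(t, splice_event("E1", "T1", "EXON_SKIP",
                                   list(skip_from = 1, skip_to = 1)))
  expect_identical(v$sequence, "ATGGCATAA")
  expect_identical(v$modified_regions,
                   data.frame(start = 6L, end = 6L))  # zero-length junction

  t2 <- transcript("T2", c("ATGAAA", "TAA"), c("GGG"))
  v2 <- apply_event(t2, splice_event("E2", "T2", "INTRON_RETAIN",
                                     list(intron = 0)))
  expect_identical(v2$sequence, "ATGAAAGGGTAA")
  expect_identical(v2$modified_regions, data.frame(start = 6L, end = 9L))

  t3 <- transcript("T3", c("ATGAAA", "CCCTAA"), c("GTAG"))
  v3 <- apply_event(t3, splice_event("E3", "T3", "ALT_3SS",
                                     list(exon = 1, shift = 3)))
  expect_identical(v3$sequence, "ATGAAATAA")
  v3b <- apply_event(t3, splice_event("E3b", "T3", "ALT_3SS",
                                      list(exon = 1, shift = -2)))
  expect_identical(v3b$sequence, "ATGAAAAGCCCTAA")
  expect_identical(v3b$modified_regions, data.frame(start = 6L, end = 8L))

  v5 <- apply_event(t3, splice_event("E5", "T3", "ALT_5SS",
                                     list(exon = 0, shift = 2)))
  expect_identical(v5$sequence, "ATGAAAGTCCCTAA")
  v5b <- apply_event(t3, splice_event("E5b", "T3", "ALT_5SS",
                                      list(exon = 0, shift = -2)))
  expect_identical(v5b$sequence, "ATGACCCTAA")

  expect_error(apply_event(t, splice_event("E9", "T1", "INTRON_RETAIN",
                                           list(intron = 5))), "invalid")
})

test_that("coordinate map reflects deletions and insertions exactly", {
  t <- transcript("T1", c("ATGGCA", "GAATTC", "TAA"), c("GT", "AG"))
  v <- apply_event(t, splice_event("E1", "T1", "EXON_SKIP",
                                   list(skip_from = 1, skip_to = 1)))
  expect_identical(map_position(v, 0), 0L)
  expect_identical(map_position(v, 12), 6L)
  expect_true(is.na(map_position(v, 7)))
  expect_error(map_position(v, 15), "out of range")
  expect_error(map_position(v, -1), "out of range")

  # unmapped set is exactly the deleted reference interval
  unmapped <- which(is.na(v$coord_map)) - 1L
  expect_identical(unmapped, 6:11)

  # insertions shift downstream mappings
  t2 <- transcript("T2", c("ATGAAA", "TAA"), c("GGG"))
  v2 <- apply_event(t2, splice_event("E2", "T2", "INTRON_RETAIN",
                                     list(intron = 0)))
  expect_identical(map_position(v2, 5), 5L)
  expect_identical(map_position(v2, 6), 9L)
})

test_that("combined application equals joint single-pass editing", {
  t <- transcript("T1", c("ATGGCA", "GAATTC", "CCAGTT", "TAA"),
                  c("GTAAG", "GTCAG", "GTTAG"))
  ce <- combined_event("C1", list(
    splice_event("a", "T1", "EXON_SKIP", list(skip_from = 1, skip_to = 1)),
    splice_event("b", "T1", "INTRON_RETAIN", list(intron = 2))))
  v <- apply_combined(t, ce)
  oracle <- spliceptide:::oracle_apply(t, ce)
  expect_identical(v$sequence, oracle$sequence)
  expect_identical(v$coord_map, oracle$coord_map)
  expect_identical(v$sequence, "ATGGCACCAGTTGTTAGTAA")

  # a singleton wrapped as combined is not constructible (needs >= 2), but
  # adjacent skips collapse to the single wider skip
  two <- apply_combined(t, combined_event("C2", list(
    splice_event("a", "T1", "EXON_SKIP", list(skip_from = 1, skip_to = 1)),
    splice_event("b", "T1", "EXON_SKIP", list(skip_from = 2, skip_to = 2)))))
  one <- apply_event(t, splice_event("w", "T1", "EXON_SKIP",
                                     list(skip_from = 1, skip_to = 2)))
  expect_identical(two$sequence, one$sequence)
  expect_identical(two$coord_map, one$coord_map)
  expect_identical(two$modified_regions, one$modified_regions)

  clash <- combined_event("C3", list(
    splice_event("a", "T1", "INTRON_RETAIN", list(intron = 1)),
    splice_event("b", "T1", "ALT_5SS", list(exon = 1, shift = 2))))
  expect_error(apply_combined(t, clash), "overlapping")
})

test_that("engine output equals the block-edit oracle on random cases", {
  set.seed(424)
  n_checked <- 0
  while (n_checked < 500) {
    t <- make_toy_transcript()
    e <- random_valid_event(t)
    if (is.null(e)) next
    v <- apply_event(t, e)
    o <- spliceptide:::oracle_apply(t, e)
    expect_identical(v$sequence, o$sequence)
    expect_identical(v$coord_map, o$coord_map)
    expect_identical(v$modified_regions, o$modified_regions)

    # length bookkeeping: |variant| = |reference| + insertions - deletions
    ins <- sum(o$modified_regions$end - o$modified_regions$start)
    del <- sum(is.na(o$coord_map))
    expect_identical(nchar(v$sequence),
                     nchar(splice_reference(t)) + ins - del)

    # monotone where defined
    mapped <- v$coord_map[!is.na(v$coord_map)]
    expect_true(all(diff(mapped) > 0))
    n_checked <- n_checked + 1
  }
})
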