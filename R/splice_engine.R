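# Splice engine: applies events to a transcript's exon/intron block
# structure in a single pass, tracking a reference->variant coordinate map
# and the intervals of the variant mRNA that differ from the reference
# splice form. Combined events are applied jointly over the block list, not
# sequentially on remapped coordinates, so the result is order-independent.

#' Reference spliced mRNA
#'
#' @param t a [transcript()].
#' @return the concatenation of the exon sequences.
#' @export
splice_reference <- function(t) {
  stopifnot(inherits(t, "transcript"))
  paste(t$exons, collapse = "")
}

# Collect per-exon/per-intron edits from a list of simple events.
collect_mods <- function(t, events) {
  n_ex <- length(t$exons)
  mods <- list(
    skip = logical(n_ex),
    trim5 = integer(n_ex), trim3 = integer(n_ex),
    ext5 = character(n_ex), ext3 = character(n_ex),
    retain = logical(max(n_ex - 1L, 0L))
  )
  mods$ext5[] <- ""
  mods$ext3[] <- ""
  for (e in events) {
    p <- e$params
    switch(e$event_type,
      EXON_SKIP = {
        mods$skip[(p$skip_from:p$skip_to) + 1L] <- TRUE
      },
      ALT_3SS = {
        i <- p$exon + 1L
        if (p$shift < 0L) {
          intr <- t$introns[i - 1L]
          mods$ext5[i] <- substr(intr, nchar(intr) + p$shift + 1L, nchar(intr))
        } else {
          mods$trim5[i] <- p$shift
        }
      },
      ALT_5SS = {
        i <- p$exon + 1L
        if (p$shift > 0L) {
          mods$ext3[i] <- substr(t$introns[i], 1L, p$shift)
        } else {
          mods$trim3[i] <- -p$shift
        }
      },
      INTRON_RETAIN = {
        mods$retain[p$intron + 1L] <- TRUE
      })
  }
  mods
}

# Single pass over the block structure. Returns the variant_transcript.
apply_mods <- function(t, events, event_id) {
  mods <- collect_mods(t, events)
  exon_len <- nchar(t$exons)
  exon_start <- c(0L, cumsum(exon_len))  # reference offsets, length n_ex + 1
  ref_len <- sum(exon_len)
  coord_map <- rep(NA_integer_, ref_len)

  pieces <- character(0)
  regions <- list()   # list of c(start, end) in variant coords
  var_pos <- 0L
  pending_junction <- FALSE

  push_insert <- function(seq) {
    if (!nchar(seq)) return(invisible())
    pieces[[length(pieces) + 1L]] <<- seq
    regions[[length(regions) + 1L]] <<- c(var_pos, var_pos + nchar(seq))
    var_pos <<- var_pos + nchar(seq)
    pending_junction <<- FALSE  # insertion interval covers the junction
  }
  push_reference <- function(seq, ref_from) {
    if (!nchar(seq)) return(invisible())
    if (pending_junction) {
      regions[[length(regions) + 1L]] <<- c(var_pos, var_pos)
      pending_junction <<- FALSE
    }
    pieces[[length(pieces) + 1L]] <<- seq
    idx <- seq.int(ref_from, length.out = nchar(seq)) + 1L
    coord_map[idx] <<- seq.int(var_pos, length.out = nchar(seq))
    var_pos <<- var_pos + nchar(seq)
  }

  for (i in seq_along(t$exons)) {
    if (mods$skip[i]) {
      pending_junction <- TRUE
    } else {
      push_insert(mods$ext5[i])
      if (mods$trim5[i] > 0L) pending_junction <- TRUE
      a <- mods$trim5[i]
      b <- exon_len[i] - mods$trim3[i]
      push_reference(substr(t$exons[i], a + 1L, b), exon_start[i] + a)
      if (mods$trim3[i] > 0L) pending_junction <- TRUE
      push_insert(mods$ext3[i])
    }
    if (i < length(t$exons) && mods$retain[i]) {
      push_insert(t$introns[i])
    }
  }
  if (pending_junction) {
    regions[[length(regions) + 1L]] <- c(var_pos, var_pos)
  }

  if (length(regions)) {
    m <- do.call(rbind, regions)
    mr <- data.frame(start = m[, 1], end = m[, 2])
    mr <- unique(mr[order(mr$start, mr$end), , drop = FALSE])
    rownames(mr) <- NULL
  } else {
    mr <- data.frame(start = integer(0), end = integer(0))
  }

  structure(list(
    sequence = paste(pieces, collapse = ""),
    source_transcript_id = t$transcript_id,
    event_id = event_id,
    modified_regions = mr,
    coord_map = coord_map,
    ref_length = ref_len
  ), class = "variant_transcript")
}

#' Apply a splicing event to a transcript
#'
#' Produces the variant mRNA plus bookkeeping: a monotone partial map from
#' reference spliced-mRNA positions to variant positions (deleted positions
#' are unmapped) and the modified regions of the variant — inserted intronic
#' or extension sequence as non-empty intervals, pure-deletion junctions as
#' zero-length intervals.
#'
#' @param t a [transcript()].
#' @param e a [splice_event()] or [combined_event()]; combined events are
#'   applied jointly in one pass over the block structure.
#' @return an object of class `variant_transcript` with fields `sequence`,
#'   `source_transcript_id`, `event_id`, `modified_regions` (data frame,
#'   0-based half-open variant coordinates), `coord_map`, `ref_length`.
#' @export
apply_event <- function(t, e) {
  stopifnot(inherits(t, "transcript"))
  if (inherits(e, "combined_event")) return(apply_combined(t, e))
  stopifnot(inherits(e, "splice_event"))
  v <- validate_event(t, e)
  if (length(v)) stop("invalid event ", e$event_id, ": ",
                      paste(v, collapse = "; "))
  apply_mods(t, list(e), e$event_id)
}

#' @rdname apply_event
#' @param c a [combined_event()].
#' @export
apply_combined <- function(t, c) {
  stopifnot(inherits(t, "transcript"), inherits(c, "combined_event"))
  v <- validate_event(t, c)
  if (length(v)) stop("invalid combined event ", c$event_id, ": ",
                      paste(v, collapse = "; "))
  apply_mods(t, c$events, c$event_id)
}

#' Map a reference mRNA position into variant coordinates
#'
#' @param v a `variant_transcript` (or any object carrying `coord_map` and
#'   `ref_length`, such as a variant protein).
#' @param ref_pos 0-based position in the reference spliced mRNA.
#' @return the 0-based variant position, or `NA` when the position was
#'   deleted by the event.
#' @export
map_position <- function(v, ref_pos) {
  stopifnot(length(ref_pos) == 1L)
  ref_pos <- as.integer(ref_pos)
  if (is.na(ref_pos) || ref_pos < 0L || ref_pos >= v$ref_length) {
    stop("ref_pos ", ref_pos, " out of range [0, ", v$ref_length, ")")
  }
  v$coord_map[ref_pos + 1L]
}

#' @export
print.variant_transcript <- function(x, ...) {
  cat("<variant_transcript>", x$event_id, "on", x$source_transcript_id,
      sprintf("(%d nt, %d modified region%s)\n", nchar(x$sequence),
              nrow(x$modified_regions),
              if (nrow(x$modified_regions) == 1L) "" else "s"))
  invisible(x)
}
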