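# Global pairwise protein alignment (Needleman-Wunsch with affine gaps,
# Gotoh recurrences) with a fully deterministic traceback so rendered
# reports are byte-stable: ties prefer diagonal, then a gap in the second
# sequence (consuming the first), then a gap in the first.
#
# Scoring: match +1, mismatch -1; a gap of length L costs
# gap_open + (L - 1) * gap_extend with gap_open = 5, gap_extend = 1.

#' Global protein alignment
#'
#' @param a,b amino-acid strings (a is rendered as the top/reference row).
#' @param match,mismatch,gap_open,gap_extend scoring parameters; `gap_open`
#'   is the cost of a gap's first residue, `gap_extend` of each further one.
#' @return list with `a_aln`, `b_aln` (gapped strings of equal length),
#'   `score`, and `identity` (matches / alignment columns).
#' @export
align_global <- function(a, b, match = 1, mismatch = -1,
                         gap_open = -5, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9

  # M: a[i] aligned to b[j]; X: gap in b (consumes a); Y: gap in a
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  if (n >= 1L) X[2:(n + 1L), 1] <- gap_open + gap_extend * (0:(n - 1L))
  if (m >= 1L) Y[1, 2:(m + 1L)] <- gap_open + gap_extend * (0:(m - 1L))

  for (i in seq_len(n)) {
    sub_i <- ifelse(bv == av[i], match, mismatch)
    Mi1 <- M[i, ]; Xi1 <- X[i, ]; Yi1 <- Y[i, ]
    Mi <- M[i + 1L, ]; Xi <- X[i + 1L, ]; Yi <- Y[i + 1L, ]
    for (j in seq_len(m)) {
      best_prev <- max(Mi1[j], Xi1[j], Yi1[j])
      Mi[j + 1L] <- best_prev + sub_i[j]
      Xi[j + 1L] <- max(Mi1[j + 1L] + gap_open, Xi1[j + 1L] + gap_extend,
                        Yi1[j + 1L] + gap_open)
      Yi[j + 1L] <- max(Mi[j] + gap_open, Yi[j] + gap_extend,
                        Xi[j] + gap_open)
    }
    M[i + 1L, ] <- Mi; X[i + 1L, ] <- Xi; Y[i + 1L, ] <- Yi
  }

  # deterministic traceback: diagonal (M) > up (X) > left (Y)
  i <- n; j <- m
  fin <- c(M[i + 1L, j + 1L], X[i + 1L, j + 1L], Y[i + 1L, j + 1L])
  state <- c("M", "X", "Y")[which.max(fin)]
  score <- max(fin)
  ra <- character(0); rb <- character(0)
  while (i > 0L || j > 0L) {
    if (state == "M") {
      s <- ifelse(bv[j] == av[i], match, mismatch)
      target <- M[i + 1L, j + 1L] - s
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state_prev <- c("M", "X", "Y")[which(abs(prev - target) < 1e-9)[1]]
      ra <- c(av[i], ra); rb <- c(bv[j], rb)
      i <- i - 1L; j <- j - 1L
      state <- state_prev
    } else if (state == "X") {
      cur <- X[i + 1L, j + 1L]
      state_prev <- if (abs(M[i, j + 1L] + gap_open - cur) < 1e-9) "M"
        else if (abs(X[i, j + 1L] + gap_extend - cur) < 1e-9) "X" else "Y"
      ra <- c(av[i], ra); rb <- c("-", rb)
      i <- i - 1L
      state <- state_prev
    } else {
      cur <- Y[i + 1L, j + 1L]
      state_prev <- if (abs(M[i + 1L, j] + gap_open - cur) < 1e-9) "M"
        else if (abs(Y[i + 1L, j] + gap_extend - cur) < 1e-9) "Y" else "X"
      ra <- c("-", ra); rb <- c(bv[j], rb)
      j <- j - 1L
      state <- state_prev
    }
    if (i == 0L && j > 0L) state <- "Y"
    if (j == 0L && i > 0L) state <- "X"
  }
  cols <- length(ra)
  matches <- sum(ra == rb & ra != "-")
  list(a_aln = paste(ra, collapse = ""), b_aln = paste(rb, collapse = ""),
       score = score,
       identity = if (cols) matches / cols else 1)
}

# Map peptide occurrences (by exact substring search) to alignment columns.
# Returns a logical mask over alignment columns for the given row.
peptide_mask <- function(aln_row, raw_seq, peptides) {
  mask <- rep(FALSE, nchar(aln_row))
  if (!length(peptides)) return(mask)
  # residue index (in raw_seq) of each alignment column; 0 for gaps
  chars <- strsplit(aln_row, "")[[1]]
  res_idx <- cumsum(chars != "-")
  res_idx[chars == "-"] <- 0L
  for (p in peptides) {
    hits <- gregexpr(p, raw_seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) {
      stop("peptide not found in its sequence: ", p)
    }
    for (h in as.integer(hits)) {
      span <- h:(h + nchar(p) - 1L)
      mask[res_idx %in% span] <- TRUE
    }
  }
  mask
}

#' Annotated alignment report
#'
#' Renders the global alignment of a variant protein against its template
#' reference protein in 60-column blocks, marking reference-supported
#' peptides on the reference row and variant-specific peptides on the
#' variant row. In the plain-text emitter a marker line of `o` (reference
#' peptides) sits above the reference row and a line of `*`
#' (variant-specific peptides) below the variant row; the HTML emitter wraps
#' the same spans in `<span class="ref-pep">` / `<span class="var-pep">`.
#' Both emitters are deterministic.
#'
#' @param v a `variant_protein` (or a list with `sequence` and
#'   `reference_protein`).
#' @param shared_peptides peptides identified on the reference protein.
#' @param variant_peptides variant-specific peptides.
#' @param format `"text"` or `"html"`.
#' @return a single string (the rendered report).
#' @export
render_alignment_report <- function(v, shared_peptides = character(0),
                                    variant_peptides = character(0),
                                    format = c("text", "html")) {
  format <- match.arg(format)
  ref <- v$reference_protein
  var <- v$sequence
  aln <- align_global(ref, var)
  ref_mask <- peptide_mask(aln$a_aln, ref, shared_peptides)
  var_mask <- peptide_mask(aln$b_aln, var, variant_peptides)
  cols <- nchar(aln$a_aln)
  rch <- strsplit(aln$a_aln, "")[[1]]
  vch <- strsplit(aln$b_aln, "")[[1]]
  mid <- ifelse(rch == vch & rch != "-", "|", " ")

  title <- if (!is.null(v$tag)) encode_header(v$tag) else "variant"
  head_lines <- c(
    sprintf("Alignment: %s", title),
    sprintf("Reference: %d aa  Variant: %d aa  Score: %g  Identity: %.1f%%",
            nchar(ref), nchar(var), aln$score, 100 * aln$identity), "")

  if (format == "text") {
    out <- head_lines
    for (from in seq(1L, cols, by = 60L)) {
      to <- min(from + 59L, cols)
      idx <- from:to
      rmarks <- paste(ifelse(ref_mask[idx], "o", " "), collapse = "")
      vmarks <- paste(ifelse(var_mask[idx], "*", " "), collapse = "")
      out <- c(out,
               if (any(ref_mask[idx])) paste0("      ", rmarks),
               sprintf("ref   %s", paste(rch[idx], collapse = "")),
               sprintf("      %s", paste(mid[idx], collapse = "")),
               sprintf("var   %s", paste(vch[idx], collapse = "")),
               if (any(var_mask[idx])) paste0("      ", vmarks),
               "")
    }
    return(paste(out, collapse = "\n"))
  }

  span_wrap <- function(chars, mask, class) {
    out <- character(0)
    open <- FALSE
    for (k in seq_along(chars)) {
      if (mask[k] && !open) { out <- c(out, sprintf("<span class=\"%s\">", class)); open <- TRUE }
      if (!mask[k] && open) { out <- c(out, "</span>"); open <- FALSE }
      out <- c(out, chars[k])
    }
    if (open) out <- c(out, "</span>")
    paste(out, collapse = "")
  }
  body <- character(0)
  for (from in seq(1L, cols, by = 60L)) {
    to <- min(from + 59L, cols)
    idx <- from:to
    body <- c(body,
              sprintf("ref   %s", span_wrap(rch[idx], ref_mask[idx], "ref-pep")),
              sprintf("      %s", paste(mid[idx], collapse = "")),
              sprintf("var   %s", span_wrap(vch[idx], var_mask[idx], "var-pep")),
              "")
  }
  paste(c("<html><head><style>",
          ".ref-pep{background:#ffb347}.var-pep{background:#ffff66}",
          "pre{font-family:monospace}",
          "</style></head><body><pre>",
          vapply(head_lines, function(x) x, character(1)),
          body,
          "</pre></body></html>"), collapse = "\n")
}
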