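# Indel annotation by global alignment of a merged fragment against its
# amplicon reference, followed by canonical left-alignment. Indel length
# follows the signed convention: affected reference length minus length of
# the alternative sequence (positive = deletion, negative = insertion).

#' Left-align one indel against a reference sequence
#'
#' Shifts a pure deletion or pure insertion to its leftmost equivalent
#' representation. Mixed events (both reference span and alternative
#' sequence non-empty) are returned unchanged.
#'
#' @param ref reference sequence (character scalar)
#' @param start0 0-based start of the affected reference interval
#' @param span number of reference bases affected (0 for an insertion)
#' @param alt alternative sequence ("" for a deletion)
#' @return list(start0, span, alt)
#' @export
left_align_indel <- function(ref, start0, span, alt) {
  rc <- strsplit(ref, "", fixed = TRUE)[[1]]
  if (span > 0 && !nzchar(alt)) {
    # deletion: shift while the base before equals the last deleted base
    while (start0 > 0 && rc[start0] == rc[start0 + span]) start0 <- start0 - 1L
  } else if (span == 0 && nzchar(alt)) {
    # insertion: rotate while the base before equals the last inserted base
    L <- nchar(alt)
    while (start0 > 0 && rc[start0] == substr(alt, L, L)) {
      alt <- paste0(rc[start0], substr(alt, 1L, L - 1L))
      start0 <- start0 - 1L
    }
  }
  list(start0 = as.integer(start0), span = as.integer(span), alt = alt)
}

# Global end-to-end alignment returning the two gapped strings.
align_global <- function(fragment, ref, config) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$match, mismatch = config$mismatch, baseOnly = FALSE
  )
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(fragment),
    subject = Biostrings::DNAString(ref),
    type = "global",
    substitutionMatrix = mat,
    gapOpening = -config$gap_open,
    gapExtension = -config$gap_extend
  )
  list(
    pattern = as.character(Biostrings::alignedPattern(aln)),
    subject = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln)
  )
}

#' Annotate indels in a merged fragment relative to its amplicon
#'
#' Globally aligns the fragment to the amplicon reference; every maximal
#' run of gap columns is emitted as one indel (adjacent deletion and
#' insertion columns merge into a single replacement event). Pure events
#' are left-aligned so that representations are canonical across staggered
#' amplicons, and positions are reported on locus coordinates
#' (`ref_start = amplicon ref_offset + in-amplicon position`).
#'
#' @param fragment merged fragment sequence
#' @param amplicon one row of an [amplicon_panel()]
#' @param config a [caller_config()]
#' @return data.frame with columns `ref_start`, `ref_span`, `alt_seq`,
#'   `length` (`ref_span - nchar(alt_seq)`); zero rows for a
#'   reference-identical fragment
#' @export
annotate_indels <- function(fragment, amplicon, config = caller_config()) {
  min_len <- nchar(amplicon$fwd_primer) + nchar(amplicon$rev_primer)
  if (nchar(fragment) < min_len) {
    stop("fragment shorter than the combined primers (", min_len, " bp) of amplicon '",
         amplicon$name, "'")
  }
  if (fragment == amplicon$ref_seq) {
    return(empty_indel_table())
  }
  aln <- align_global(fragment, amplicon$ref_seq, config)
  p <- strsplit(aln$pattern, "", fixed = TRUE)[[1]]
  s <- strsplit(aln$subject, "", fixed = TRUE)[[1]]
  is_gap <- p == "-" | s == "-"
  if (!any(is_gap)) {
    return(empty_indel_table())
  }
  runs <- rle(is_gap)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  # reference position (0-based, in-amplicon) at the start of each column
  ref_consumed <- cumsum(s != "-")
  out <- list()
  for (k in which(runs$values)) {
    cols <- starts[k]:ends[k]
    ref_start <- if (starts[k] == 1L) 0L else ref_consumed[starts[k] - 1L]
    del_cols <- cols[p[cols] == "-"]
    ins_cols <- cols[s[cols] == "-"]
    span <- length(del_cols)
    alt <- paste(p[ins_cols], collapse = "")
    la <- left_align_indel(amplicon$ref_seq, ref_start, span, alt)
    out[[length(out) + 1L]] <- data.frame(
      ref_start = amplicon$ref_offset + la$start0,
      ref_span = la$span,
      alt_seq = la$alt,
      length = la$span - nchar(la$alt),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res[order(res$ref_start), , drop = FALSE]
}

empty_indel_table <- function() {
  data.frame(
    ref_start = integer(0), ref_span = integer(0),
    alt_seq = character(0), length = integer(0),
    stringsAsFactors = FALSE
  )
}
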