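# Amplicon deep-sequencing indel caller:
# demultiplex -> merge -> collapse -> predominant-per-length -> annotate ->
# threshold across amplicons -> clonality summary.

#' Demultiplex read pairs by exact primer match
#'
#' A pair is assigned to an amplicon iff read 1 starts with its forward
#' primer and read 2 with its reverse primer, allowing no mismatches; the
#' swapped orientation (read 1 = reverse primer) is also accepted, in which
#' case the mates are swapped so that downstream code always sees the
#' forward-primer read first. Every pair is assigned at most once (panel
#' order breaks the — structurally impossible, see [amplicon_panel()] —
#' case of a pair matching two amplicons).
#'
#' @param pairs pair table (see [read_fastq_pairs()])
#' @param panel an [amplicon_panel()]
#' @return list with `assigned` (named list of pair tables, one per
#'   amplicon) and `unassigned` (count); counts conserve:
#'   `sum(assigned) + unassigned == nrow(pairs)`
#' @export
demultiplex_reads <- function(pairs, panel) {
  validate_panel(panel)
  n <- nrow(pairs)
  taken <- rep(FALSE, n)
  assigned <- stats::setNames(vector("list", nrow(panel)), panel$name)
  for (i in seq_len(nrow(panel))) {
    fwd <- panel$fwd_primer[i]
    rev <- panel$rev_primer[i]
    straight <- !taken & startsWith(pairs$seq1, fwd) & startsWith(pairs$seq2, rev)
    swapped <- !taken & !straight &
      startsWith(pairs$seq1, rev) & startsWith(pairs$seq2, fwd)
    sub <- pairs[straight | swapped, , drop = FALSE]
    sw <- swapped[straight | swapped]
    if (any(sw)) {
      tmp <- sub[sw, c("seq2", "qual2", "seq1", "qual1")]
      sub[sw, c("seq1", "qual1", "seq2", "qual2")] <- tmp
    }
    assigned[[i]] <- sub
    taken <- taken | straight | swapped
  }
  list(assigned = assigned, unassigned = sum(!taken))
}

#' Merge mate pairs by overlap consensus
#'
#' The reverse read is reverse-complemented and slid against the forward
#' read; the accepted overlap maximises matching bases subject to an
#' overlap of at least `min_merge_overlap` and a mismatch fraction of at
#' most `max_merge_mismatch_frac` (ties to the larger overlap). At
#' disagreeing positions the base with the higher quality wins. The merged
#' length is `nchar(fwd) + nchar(rev) - overlap`. Pairs with no admissible
#' overlap fail (NA).
#'
#' @param fwd,rev read sequences (character vectors, same length)
#' @param fwd_qual,rev_qual Phred+33 quality strings
#' @param config a [caller_config()]
#' @return character vector of merged sequences, NA where merging failed
#' @export
merge_pairs <- function(fwd, rev, fwd_qual, rev_qual, config = caller_config()) {
  stopifnot(length(fwd) == length(rev))
  cpp_merge_pairs(fwd, fwd_qual, rev, rev_qual,
                  config$min_merge_overlap, config$max_merge_mismatch_frac)
}

#' Merge a single mate pair
#'
#' @inheritParams merge_pairs
#' @return the merged sequence, or NA on merge failure
#' @export
merge_pair <- function(fwd, rev, fwd_qual = NULL, rev_qual = NULL,
                       config = caller_config()) {
  if (is.null(fwd_qual)) fwd_qual <- strrep("F", nchar(fwd))
  if (is.null(rev_qual)) rev_qual <- strrep("F", nchar(rev))
  merge_pairs(fwd, rev, fwd_qual, rev_qual, config)[1]
}

#' Collapse identical merged fragments and drop rare ones
#'
#' Identical sequences within an amplicon are combined with summed counts;
#' fragments occurring fewer than `min_fragment_count` times are removed
#' (the threshold itself is retained). Output is sorted by descending
#' count.
#'
#' @param merged data.frame with columns `amplicon`, `seq` (one row per
#'   successfully merged pair)
#' @param config a [caller_config()]
#' @return data.frame with columns `amplicon`, `seq`, `count`
#' @export
collapse_fragments <- function(merged, config = caller_config()) {
  if (nrow(merged) == 0) {
    return(data.frame(amplicon = character(0), seq = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(merged))),
    by = list(amplicon = merged$amplicon, seq = merged$seq),
    FUN = sum
  )
  agg <- agg[agg$count >= config$min_fragment_count, , drop = FALSE]
  agg <- agg[order(-agg$count, agg$amplicon, agg$seq), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Keep the predominant fragment per length
#'
#' Within each (amplicon, fragment length) group only the most frequent
#' sequence is retained; ties are broken by the lexicographically smallest
#' sequence. Discarded fragments are attached as attribute `"discarded"`.
#'
#' @param fragments collapsed fragment table (see [collapse_fragments()])
#' @return the retained fragment table, with attribute `discarded`
#' @export
select_predominant_per_length <- function(fragments) {
  if (nrow(fragments) == 0) {
    attr(fragments, "discarded") <- fragments
    return(fragments)
  }
  len <- nchar(fragments$seq)
  ord <- order(fragments$amplicon, len, -fragments$count, fragments$seq)
  f <- fragments[ord, , drop = FALSE]
  key <- paste(f$amplicon, nchar(f$seq))
  keep <- !duplicated(key)
  retained <- f[keep, , drop = FALSE]
  retained <- retained[order(-retained$count, retained$amplicon, retained$seq), , drop = FALSE]
  rownames(retained) <- NULL
  discarded <- f[!keep, , drop = FALSE]
  rownames(discarded) <- NULL
  attr(retained, "discarded") <- discarded
  retained
}

#' Call indels across staggered amplicons
#'
#' Each non-reference fragment is annotated by global alignment; indels
#' identified by the same left-aligned (ref_start, ref_span, alt_seq) are
#' merged across amplicons. Per-amplicon read fractions are supporting
#' fragment counts divided by that amplicon's total merged reads
#' (`totals`). An indel is called when it reaches `min_fraction` in each
#' of at least `min_amplicons` amplicons (or, with
#' `per_amplicon_fraction = FALSE`, when present in `min_amplicons`
#' amplicons at a pooled fraction of `min_fraction`).
#'
#' @param fragments collapsed (and typically predominant-per-length)
#'   fragment table
#' @param panel an [amplicon_panel()]
#' @param totals named integer vector: merged read count per amplicon,
#'   computed before the rare-fragment filter (see [caller_config()]
#'   `denominator`)
#' @param config a [caller_config()]
#' @return data.frame of called indels, sorted by descending maximum
#'   fraction, with columns `ref_start`, `ref_span`, `alt_seq`, `length`,
#'   `n_amplicons`, `amplicons` (comma-separated), `max_fraction`,
#'   `mean_fraction`, and a list-column `fractions` (named per-amplicon
#'   fraction vectors). Attribute `"all_indels"` holds the same table
#'   before thresholding.
#' @export
call_indels <- function(fragments, panel, totals, config = caller_config()) {
  empty <- data.frame(
    ref_start = integer(0), ref_span = integer(0), alt_seq = character(0),
    length = integer(0), n_amplicons = integer(0), amplicons = character(0),
    max_fraction = numeric(0), mean_fraction = numeric(0),
    stringsAsFactors = FALSE
  )
  empty$fractions <- list()
  zero <- names(totals)[totals == 0]
  if (length(zero)) {
    warning("amplicon(s) with zero merged reads excluded from denominators: ",
            paste(zero, collapse = ", "))
    totals <- totals[totals > 0]
  }
  fragments <- fragments[fragments$amplicon %in% names(totals), , drop = FALSE]
  if (nrow(fragments) == 0) {
    attr(empty, "all_indels") <- empty
    return(empty)
  }

  # annotate each fragment, accumulate per-(indel, amplicon) supporting counts
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(fragments))) {
    amp <- panel[panel$name == fragments$amplicon[i], , drop = FALSE]
    if (nrow(amp) != 1) stop("fragment assigned to unknown amplicon: ", fragments$amplicon[i])
    ind <- annotate_indels(fragments$seq[i], amp, config)
    if (nrow(ind) == 0) next
    for (j in seq_len(nrow(ind))) {
      key <- paste(ind$ref_start[j], ind$ref_span[j], ind$alt_seq[j], sep = "|")
      rec <- if (!is.null(acc[[key]])) acc[[key]] else {
        list(ref_start = ind$ref_start[j], ref_span = ind$ref_span[j],
             alt_seq = ind$alt_seq[j], length = ind$length[j],
             counts = stats::setNames(numeric(0), character(0)))
      }
      a <- fragments$amplicon[i]
      rec$counts[a] <- sum(rec$counts[a], fragments$count[i], na.rm = TRUE)
      acc[[key]] <- rec
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0) {
    attr(empty, "all_indels") <- empty
    return(empty)
  }

  rows <- lapply(keys, function(k) {
    rec <- acc[[k]]
    fr <- rec$counts / totals[names(rec$counts)]
    names(fr) <- names(rec$counts)
    data.frame(
      ref_start = rec$ref_start, ref_span = rec$ref_span,
      alt_seq = rec$alt_seq, length = rec$length,
      n_amplicons = length(fr),
      amplicons = paste(sort(names(fr)), collapse = ","),
      max_fraction = max(fr), mean_fraction = mean(fr),
      pooled_fraction = sum(rec$counts) / sum(totals),
      stringsAsFactors = FALSE
    )
  })
  all_ind <- do.call(rbind, rows)
  all_ind$fractions <- lapply(keys, function(k) {
    rec <- acc[[k]]
    rec$counts / totals[names(rec$counts)]
  })
  all_ind <- all_ind[order(-all_ind$max_fraction, all_ind$ref_start), , drop = FALSE]
  rownames(all_ind) <- NULL

  called <- if (config$per_amplicon_fraction) {
    vapply(all_ind$fractions, function(fr) {
      sum(fr >= config$min_fraction) >= config$min_amplicons
    }, logical(1))
  } else {
    all_ind$n_amplicons >= config$min_amplicons &
      all_ind$pooled_fraction >= config$min_fraction
  }
  res <- all_ind[called, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "all_indels") <- all_ind
  res
}

#' Summarise clonality of called indels
#'
#' Counts distinct called indels longer than
#' `min_indel_len_for_clonality` (strict, in absolute signed length) and
#' reports the read share of the k most frequent indels for k = 1..5:
#' the sum of the top-k mean-across-amplicon fractions divided by the sum
#' over all counted indels. Shares are non-decreasing in k.
#'
#' @param calls a call table from [call_indels()] (one sample)
#' @param config a [caller_config()]
#' @return list with `n_distinct_indels` and `top_k_read_share` (numeric
#'   of length 5, NA when no indels qualify)
#' @export
clonality_summary <- function(calls, config = caller_config()) {
  keep <- abs(calls$length) > config$min_indel_len_for_clonality
  calls <- calls[keep, , drop = FALSE]
  n <- nrow(calls)
  if (n == 0) {
    return(list(n_distinct_indels = 0L,
                top_k_read_share = stats::setNames(rep(NA_real_, 5), paste0("top", 1:5))))
  }
  fr <- sort(calls$mean_fraction, decreasing = TRUE)
  shares <- vapply(1:5, function(k) sum(fr[seq_len(min(k, n))]) / sum(fr), numeric(1))
  list(n_distinct_indels = n,
       top_k_read_share = stats::setNames(shares, paste0("top", 1:5)))
}

#' Run the full amplicon indel-calling chain on one sample
#'
#' Demultiplexes, merges, collapses, selects predominant fragments per
#' length, calls indels across amplicons and summarises clonality.
#'
#' @param pairs pair table, or `r1`/`r2` FASTQ paths given as
#'   `c(r1, r2)`
#' @param panel an [amplicon_panel()]
#' @param config a [caller_config()]
#' @return list with `calls`, `clonality`, `totals` (merged reads per
#'   amplicon), and `stats` (pair accounting: input, assigned, unassigned,
#'   merged, merge_failed)
#' @export
call_amplicon_sample <- function(pairs, panel, config = caller_config()) {
  if (is.character(pairs) && length(pairs) == 2) {
    pairs <- read_fastq_pairs(pairs[1], pairs[2])
  }
  dm <- demultiplex_reads(pairs, panel)
  merged_list <- lapply(names(dm$assigned), function(a) {
    sub <- dm$assigned[[a]]
    if (nrow(sub) == 0) {
      return(data.frame(amplicon = character(0), seq = character(0),
                        stringsAsFactors = FALSE))
    }
    m <- merge_pairs(sub$seq1, sub$seq2, sub$qual1, sub$qual2, config)
    data.frame(amplicon = a, seq = m[!is.na(m)], stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, merged_list)
  n_assigned <- sum(vapply(dm$assigned, nrow, integer(1)))
  totals_pre <- vapply(panel$name, function(a) {
    sum(merged$amplicon == a)
  }, integer(1))

  collapsed <- collapse_fragments(merged, config)
  predominant <- select_predominant_per_length(collapsed)
  totals <- if (config$denominator == "pre_filter") {
    totals_pre
  } else {
    vapply(panel$name, function(a) {
      as.integer(sum(collapsed$count[collapsed$amplicon == a]))
    }, integer(1))
  }
  calls <- call_indels(predominant, panel, totals, config)
  list(
    calls = calls,
    clonality = clonality_summary(calls, config),
    totals = totals,
    fragments = predominant,
    stats = c(
      input = nrow(pairs),
      assigned = n_assigned,
      unassigned = dm$unassigned,
      merged = nrow(merged),
      merge_failed = n_assigned - nrow(merged)
    )
  )
}
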