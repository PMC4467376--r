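# Genome-wide protospacer matching within a Hamming mismatch budget, and
# the two recurrence screens used to look for clonally enriched off-target
# deletions.

#' Scan a genome for guide protospacer matches
#'
#' Reports every 20-bp window, on both strands, whose Hamming distance to
#' the protospacer is at most `max_mm`. Windows containing N never match.
#' The PAM constraint is off by default (the bare 20-mer is matched, as in
#' mismatch-mapping tools such as SeqMap); with `require_pam` an NGG
#' immediately 3' of the protospacer is additionally required.
#'
#' @param protospacer 20-mer guide sequence (A/C/G/T)
#' @param genome named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a FASTA path
#' @param max_mm mismatch budget (Hamming; no bulges)
#' @param require_pam require an NGG immediately 3' of the match
#' @return data.frame of hits with columns `chrom`, `pos` (0-based start
#'   of the 20-mer on the + strand), `strand`, `mismatches`,
#'   `matched_seq` (+-strand sequence of the window), sorted by
#'   (chrom, pos, strand)
#' @export
scan_genome <- function(protospacer, genome, max_mm = 3L, require_pam = FALSE) {
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) != 20L || !is_dna(protospacer)) {
    stop("protospacer must be a 20-mer over A/C/G/T")
  }
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_genome_fasta(genome)
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  if (length(genome) == 0) return(empty_hits())
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))

  pat_f <- Biostrings::DNAString(protospacer)
  pat_r <- Biostrings::reverseComplement(pat_f)
  hits <- list()
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    for (str in c("+", "-")) {
      pat <- if (str == "+") pat_f else pat_r
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm,
                                    with.indels = FALSE, fixed = TRUE)
      if (length(m) == 0) next
      st <- Biostrings::start(m)
      mseq <- as.character(Biostrings::extractAt(
        subj, IRanges::IRanges(st, width = 20L)
      ))
      mm <- vapply(mseq, function(s) {
        if (grepl("[^ACGT]", s)) return(NA_integer_)
        hamming(as.character(pat), s)
      }, integer(1), USE.NAMES = FALSE)
      ok <- !is.na(mm) & mm <= max_mm
      if (require_pam) {
        ok <- ok & has_pam(as.character(subj), st - 1L, str)
      }
      if (!any(ok)) next
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom, pos = st[ok] - 1L, strand = str,
        mismatches = mm[ok], matched_seq = mseq[ok],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(hits) == 0) return(empty_hits())
  out <- do.call(rbind, hits)
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

has_pam <- function(chrom_seq, pos0, strand) {
  # NGG immediately 3' of the 20-mer (on the matched strand)
  n <- nchar(chrom_seq)
  if (strand == "+") {
    p <- pos0 + 20L
    ok <- p + 3L <= n
    pam <- substr(rep(chrom_seq, length(pos0)), p + 2L, p + 3L)
    ok & pam == "GG"
  } else {
    ok <- pos0 - 3L >= 0L
    pam <- substr(rep(chrom_seq, length(pos0)), pos0 - 2L, pos0 - 1L)
    ok & pam == "CC"
  }
}

empty_hits <- function() {
  data.frame(chrom = character(0), pos = integer(0), strand = character(0),
             mismatches = integer(0), matched_seq = character(0),
             stringsAsFactors = FALSE)
}

#' Partition deletion events by proximity to guide-matched sites
#'
#' An event is guide-matched iff some protospacer hit (within `max_mm`
#' mismatches) lies within `window` bp of either breakpoint. Matched
#' events overlapping the declared on-target interval are `on_target`;
#' other matched events are `off_target_matched`; the rest `unmatched`.
#'
#' @param events event table (`chrom`, `start`, `end`)
#' @param protospacer 20-mer guide sequence
#' @param genome genome as for [scan_genome()]
#' @param on_target list/row with `chrom`, `start`, `end` declaring the
#'   intended target interval
#' @param max_mm mismatch budget (default 3)
#' @param window maximum breakpoint-to-site distance in bp (default 30:
#'   guide length plus 10, covering cut-site offset and resection)
#' @return `events` with an added `category` column
#' @export
match_deletions_to_guide <- function(events, protospacer, genome, on_target,
                                     max_mm = 3L, window = 30L) {
  hits <- scan_genome(protospacer, genome, max_mm = max_mm)
  matched <- vapply(seq_len(nrow(events)), function(i) {
    sel <- hits$chrom == events$chrom[i]
    if (!any(sel)) return(FALSE)
    hs <- hits$pos[sel]; he <- hits$pos[sel] + 20L
    near <- function(p) pmax(hs - p, p - he + 1L, 0L) <= window
    any(near(events$start[i]) | near(events$end[i]))
  }, logical(1))
  on <- events$chrom == on_target$chrom &
    events$start < on_target$end & events$end > on_target$start
  events$category <- ifelse(matched & on, "on_target",
                            ifelse(matched, "off_target_matched", "unmatched"))
  events
}

#' Cluster deletion events into loci
#'
#' Events whose `pad`-extended intervals overlap are merged transitively;
#' each event belongs to exactly one cluster. Cluster bounds are the union
#' (min start, max end) of the member events, unpadded.
#'
#' @param events event table with a `sample` column
#' @param pad interval padding in bp (default 5)
#' @return data.frame of clusters with columns `chrom`, `start`, `end`,
#'   `n_samples`, `n_events`, and a list-column `members` (per-cluster
#'   event tables)
#' @export
cluster_loci <- function(events, pad = 5L) {
  if (nrow(events) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_samples = integer(0), n_events = integer(0),
                      stringsAsFactors = FALSE)
    out$members <- list()
    return(out)
  }
  gr <- GenomicRanges::GRanges(
    events$chrom,
    IRanges::IRanges(pmax(events$start - pad, 0L) + 1L, events$end + pad)
  )
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  ov <- GenomicRanges::findOverlaps(gr, red)
  cl <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  rows <- lapply(sort(unique(cl)), function(k) {
    mem <- events[cl == k, , drop = FALSE]
    rownames(mem) <- NULL
    data.frame(
      chrom = mem$chrom[1],
      start = min(mem$start), end = max(mem$end),
      n_samples = length(unique(mem$sample)),
      n_events = nrow(mem),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(sort(unique(cl)), function(k) {
    mem <- events[cl == k, , drop = FALSE]
    rownames(mem) <- NULL
    mem
  })
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Loci recurrently mutated in every sample
#'
#' Returns the clusters that contain at least one event from every tumour
#' sample — the first off-target screen: a true off-target site under
#' sustained Cas9 exposure should be hit independently in each tumour.
#'
#' @param clusters cluster table from [cluster_loci()]
#' @param all_samples character vector of all tumour sample identifiers
#'   (at least 2)
#' @return the qualifying clusters
#' @export
recurrent_loci <- function(clusters, all_samples) {
  if (length(all_samples) < 2) stop("recurrence screening needs >= 2 samples")
  keep <- vapply(clusters$members, function(mem) {
    all(all_samples %in% mem$sample)
  }, logical(1))
  out <- clusters[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Loci with multiple distinct deletions in one sample
#'
#' Returns the clusters where some single sample contributes two or more
#' distinct (start, end) deletions — the second off-target screen:
#' independent editing events in one polyclonal tumour mark a locus under
#' recurrent cutting.
#'
#' @param clusters cluster table from [cluster_loci()]
#' @return the qualifying clusters
#' @export
multi_deletion_loci <- function(clusters) {
  keep <- vapply(clusters$members, function(mem) {
    any(vapply(split(mem, mem$sample), function(g) {
      nrow(unique(g[, c("start", "end")])) >= 2
    }, logical(1)))
  }, logical(1))
  out <- clusters[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
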