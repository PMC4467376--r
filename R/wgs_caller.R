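# WGS deletion extraction and filtering. Alignment segments are held as a
# plain data.frame (one row per SAM record): read_id (mate-resolved),
# chrom, pos (0-based leftmost), cigar, strand, is_supplementary,
# mate_pos (0-based or NA), seq, qual. Both mate ends are treated as
# independent observations.

#' Read alignment segments from a SAM or BAM file
#'
#' SAM input is converted on the fly via Rsamtools. Mates are resolved to
#' distinct read ids (`qname/1`, `qname/2`) so each end is an independent
#' observation.
#'
#' @param path path to a coordinate-sorted SAM or BAM file
#' @return a segment table (see module header)
#' @export
read_alignment_segments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  } else {
    bam <- path
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mpos"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  ga <- GenomicAlignments::readGAlignments(bam, param = param, use.names = FALSE)
  mc <- S4Vectors::mcols(ga)
  mate <- ifelse(bitwAnd(mc$flag, 128L) > 0L, "/2", "/1")
  data.frame(
    read_id = paste0(mc$qname, mate),
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    pos = GenomicAlignments::start(ga) - 1L,
    cigar = GenomicAlignments::cigar(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    is_supplementary = bitwAnd(mc$flag, 2048L) > 0L,
    mate_pos = ifelse(is.na(mc$mpos), NA_integer_, mc$mpos - 1L),
    stringsAsFactors = FALSE
  )
}

# Parse a segment table's CIGARs into per-segment op/length lists plus
# derived quantities (vectorised via GenomicAlignments).
parse_cigars <- function(segments) {
  bad <- !grepl("^([0-9]+[MIDSH])+$", segments$cigar)
  if (any(bad)) {
    stop("unknown or unsupported CIGAR operation in record of read ",
         segments$read_id[which(bad)[1]], " (", segments$cigar[which(bad)[1]], ")")
  }
  list(
    ops = GenomicAlignments::explodeCigarOps(segments$cigar),
    lens = GenomicAlignments::explodeCigarOpLengths(segments$cigar)
  )
}

#' Extract per-read deletion and insertion observations
#'
#' Two evidence channels, mirroring the split-read/CIGAR model:
#' \itemize{
#'   \item CIGAR: within one segment, each D run flanked by M runs yields a
#'     deletion (`start` = reference position after the preceding M run);
#'     each I run flanked by M runs yields an insertion observation.
#'   \item Split reads: exactly two segments of one read end on the same
#'     chromosome and strand, with consistent reference/query order and a
#'     positive reference gap no larger than `max_gap`, yield a deletion
#'     spanning the gap.
#' }
#' Reads with a single M run and no split partner contribute nothing.
#' Every observation records the mapping-stretch lengths of its read (for
#' [filter_read_level()]) and its read's outer alignment coordinates plus
#' mate position (for [deduplicate_and_combine()]).
#'
#' @param segments a segment table (see [read_alignment_segments()])
#' @param max_gap maximum reference gap accepted when pairing split
#'   segments (default 1e5, the deletion size cap)
#' @return list with `deletions` and `insertions` observation tables
#' @export
extract_candidate_indels <- function(segments, max_gap = 100000L) {
  cg <- parse_cigars(segments)
  dels <- list(); inss <- list()

  ref_span <- vapply(seq_len(nrow(segments)), function(i) {
    sum(cg$lens[[i]][cg$ops[[i]] %in% c("M", "D")])
  }, numeric(1))
  lead_clip <- vapply(seq_len(nrow(segments)), function(i) {
    o <- cg$ops[[i]]; l <- cg$lens[[i]]
    k <- 0L
    for (j in seq_along(o)) { if (o[j] %in% c("S", "H")) k <- k + l[j] else break }
    k
  }, numeric(1))
  total_m <- vapply(seq_len(nrow(segments)), function(i) {
    sum(cg$lens[[i]][cg$ops[[i]] == "M"])
  }, numeric(1))

  # --- CIGAR channel -------------------------------------------------------
  for (i in seq_len(nrow(segments))) {
    o <- cg$ops[[i]]; l <- cg$lens[[i]]
    m_idx <- which(o == "M")
    if (length(m_idx) < 2) next
    m_runs <- l[m_idx]
    refpos <- segments$pos[i]
    for (j in seq_along(o)) {
      adv <- if (o[j] %in% c("M", "D")) l[j] else 0L
      if (o[j] %in% c("D", "I") &&
          any(m_idx < j) && any(m_idx > j)) {
        obs <- data.frame(
          read_id = segments$read_id[i],
          chrom = segments$chrom[i],
          start = if (o[j] == "D") refpos else refpos,
          end = if (o[j] == "D") refpos + l[j] else refpos,
          ins_len = if (o[j] == "I") l[j] else 0L,
          type = if (o[j] == "D") "deletion" else "insertion",
          source = "cigar",
          flank_left = l[max(m_idx[m_idx < j])],
          flank_right = l[min(m_idx[m_idx > j])],
          min_m_run = min(m_runs),
          total_m = total_m[i],
          outer_start = segments$pos[i],
          outer_end = segments$pos[i] + ref_span[i],
          mate_pos = segments$mate_pos[i],
          stringsAsFactors = FALSE
        )
        if (o[j] == "D") dels[[length(dels) + 1L]] <- obs
        else inss[[length(inss) + 1L]] <- obs
      }
      refpos <- refpos + adv
    }
  }

  # --- split-read channel --------------------------------------------------
  split_ids <- names(which(table(segments$read_id) == 2))
  for (id in split_ids) {
    idx <- which(segments$read_id == id)
    if (segments$pos[idx[1]] > segments$pos[idx[2]]) idx <- rev(idx)
    a <- idx[1]; b <- idx[2]
    if (segments$chrom[a] != segments$chrom[b]) next
    if (segments$strand[a] != segments$strand[b]) next
    # reference order: a left of b with a positive gap
    gap_start <- segments$pos[a] + ref_span[a]
    gap_end <- segments$pos[b]
    if (gap_end <= gap_start || gap_end - gap_start > max_gap) next
    # query order must agree with reference order
    qa <- lead_clip[a]; qb <- lead_clip[b]
    if (segments$strand[a] == "-") { tmpq <- qa; qa <- qb; qb <- tmpq }
    if (!(qa < qb)) next
    dels[[length(dels) + 1L]] <- data.frame(
      read_id = id,
      chrom = segments$chrom[a],
      start = gap_start, end = gap_end, ins_len = 0L,
      type = "deletion", source = "split",
      flank_left = total_m[a], flank_right = total_m[b],
      min_m_run = min(total_m[a], total_m[b]),
      total_m = total_m[a] + total_m[b],
      outer_start = segments$pos[a],
      outer_end = segments$pos[b] + ref_span[b],
      mate_pos = segments$mate_pos[a],
      stringsAsFactors = FALSE
    )
  }

  empty_obs <- data.frame(
    read_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), ins_len = integer(0), type = character(0),
    source = character(0), flank_left = numeric(0), flank_right = numeric(0),
    min_m_run = numeric(0), total_m = numeric(0), outer_start = integer(0),
    outer_end = integer(0), mate_pos = integer(0), stringsAsFactors = FALSE
  )
  list(
    deletions = if (length(dels)) do.call(rbind, dels) else empty_obs,
    insertions = if (length(inss)) do.call(rbind, inss) else empty_obs
  )
}

#' Read-level filter on mapping stretches
#'
#' An observation is kept iff every mapping stretch (CIGAR M run) of its
#' read is at least `min_stretch` bp and at least `min_mapped_total` bases
#' are mapped in total (for split observations: across both segments).
#'
#' @param observations an observation table from
#'   [extract_candidate_indels()]
#' @param config a [wgs_config()]
#' @return the observations that pass
#' @export
filter_read_level <- function(observations, config = wgs_config()) {
  keep <- observations$min_m_run >= config$min_stretch &
    observations$flank_left >= config$min_stretch &
    observations$flank_right >= config$min_stretch &
    observations$total_m >= config$min_mapped_total
  observations[keep, , drop = FALSE]
}

#' Combine observations into deletion events, removing PCR duplicates
#'
#' Observations indicating the same deletion (identical chrom, start, end)
#' are combined into one event. Putative PCR duplicates — observations
#' whose reads share identical outer alignment coordinates on both ends
#' (alignment start/end plus mate position) — count once towards support.
#'
#' @param observations deletion observations (one sample)
#' @param sample sample identifier attached to the events
#' @return event table with columns `sample`, `chrom`, `start`, `end`,
#'   `size`, `support`, `source`
#' @export
deduplicate_and_combine <- function(observations, sample = "sample") {
  if (nrow(observations) == 0) {
    return(data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), size = integer(0),
                      support = integer(0), source = character(0),
                      stringsAsFactors = FALSE))
  }
  dup_key <- paste(observations$chrom, observations$start, observations$end,
                   observations$outer_start, observations$outer_end,
                   ifelse(is.na(observations$mate_pos), "NA", observations$mate_pos))
  obs <- observations[!duplicated(dup_key), , drop = FALSE]
  ev_key <- paste(obs$chrom, obs$start, obs$end)
  split_obs <- split(obs, ev_key)
  rows <- lapply(split_obs, function(g) {
    data.frame(
      sample = sample,
      chrom = g$chrom[1], start = g$start[1], end = g$end[1],
      size = g$end[1] - g$start[1],
      support = nrow(g),
      source = if (any(g$source == "cigar")) "cigar" else "split",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-position mapped-base coverage from alignment segments
#'
#' Depth of CIGAR M bases per reference position, combined across the
#' supplied segments (typically all control samples pooled).
#'
#' @param segments a segment table
#' @param seqlengths named integer vector of chromosome lengths
#' @return an `RleList` (one run-length vector per chromosome), 1-based
#'   positions
#' @export
compute_coverage <- function(segments, seqlengths) {
  if (nrow(segments) == 0) {
    return(IRanges::RleList(lapply(seqlengths, function(l) S4Vectors::Rle(0L, l))))
  }
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    segments$cigar, ops = "M", pos = segments$pos + 1L, reduce.ranges = TRUE
  )
  gr <- GenomicRanges::GRanges(
    rep(segments$chrom, lengths(rr)),
    unlist(rr),
    seqlengths = seqlengths
  )
  GenomicRanges::coverage(gr)
}

coverage_at <- function(cov, chrom, pos0) {
  # depth at a 0-based position; positions outside the assembly count as 0
  vapply(seq_along(chrom), function(i) {
    v <- cov[[chrom[i]]]
    p <- pos0[i] + 1L
    if (is.null(v) || p < 1L || p > length(v)) 0 else as.numeric(v[p])
  }, numeric(1))
}

#' Filter deletion events against controls and annotation tracks
#'
#' The five-stage cascade, applied in a fixed order so per-filter drop
#' tallies are reproducible:
#' \enumerate{
#'   \item size: retained iff `min_size <= size <= max_size`;
#'   \item control breakpoints: dropped if either breakpoint lies within
#'     `control_pad` bp of any breakpoint of the pooled control events;
#'   \item polymorphic: dropped if the event matches a known polymorphic
#'     indel interval at reciprocal overlap >= `polymorphic_identity`;
#'   \item repeats: dropped if either breakpoint (± `control_pad`)
#'     overlaps an annotated simple-repeat interval;
#'   \item coverage: dropped if either breakpoint lies at a position whose
#'     combined control coverage strictly exceeds `max_control_coverage`.
#' }
#' Both tracks are required arguments (they may be empty tables): passing
#' `NULL` is an error, so a forgotten track cannot silently disable a
#' filter.
#'
#' @param events event table (see [deduplicate_and_combine()])
#' @param control_events pooled control event table (same columns)
#' @param polymorphic,repeats interval tables with columns `chrom`,
#'   `start`, `end` (0-based half-open; see [read_bed()])
#' @param control_coverage an `RleList` from [compute_coverage()], or NULL
#'   to skip the coverage filter explicitly
#' @param config a [wgs_config()]
#' @return list with `retained` (event table), `dropped` (event table with
#'   a `reason` column) and `tally` (named integer vector over the five
#'   filters); `nrow(retained) + sum(tally) == nrow(events)`
#' @export
filter_deletions <- function(events, control_events, polymorphic, repeats,
                             control_coverage, config = wgs_config()) {
  if (is.null(polymorphic) || is.null(repeats)) {
    stop("polymorphic and repeat tracks are required (pass empty tables, not NULL)")
  }
  stages <- c("size", "control_breakpoint", "polymorphic", "repeat", "coverage")
  tally <- stats::setNames(integer(5), stages)
  reason <- rep(NA_character_, nrow(events))

  fail_size <- events$size < config$min_size | events$size > config$max_size

  ctrl_bp <- c(control_events$start, control_events$end)
  near_ctrl <- function(p) {
    if (length(ctrl_bp) == 0) return(rep(FALSE, length(p)))
    vapply(p, function(x) any(abs(x - ctrl_bp) <= config$control_pad), logical(1))
  }
  fail_ctrl <- near_ctrl(events$start) | near_ctrl(events$end)

  fail_poly <- matches_polymorphic(events, polymorphic, config)

  rep_hit <- function(p, chrom) {
    if (nrow(repeats) == 0) return(rep(FALSE, length(p)))
    vapply(seq_along(p), function(i) {
      sel <- repeats$chrom == chrom[i]
      any(p[i] + config$control_pad >= repeats$start[sel] &
            p[i] - config$control_pad < repeats$end[sel])
    }, logical(1))
  }
  fail_rep <- rep_hit(events$start, events$chrom) | rep_hit(events$end, events$chrom)

  fail_cov <- if (is.null(control_coverage)) {
    rep(FALSE, nrow(events))
  } else {
    coverage_at(control_coverage, events$chrom, events$start) > config$max_control_coverage |
      coverage_at(control_coverage, events$chrom, events$end) > config$max_control_coverage
  }

  fails <- cbind(fail_size, fail_ctrl, fail_poly, fail_rep, fail_cov)
  first_fail <- apply(fails, 1, function(x) if (any(x)) which(x)[1] else NA_integer_)
  if (nrow(events) == 0) first_fail <- integer(0)
  dropped <- !is.na(first_fail)
  reason[dropped] <- stages[first_fail[dropped]]
  for (s in seq_along(stages)) {
    tally[s] <- sum(first_fail == s, na.rm = TRUE)
  }
  drop_tab <- events[dropped, , drop = FALSE]
  if (nrow(drop_tab)) drop_tab$reason <- reason[dropped]
  else drop_tab$reason <- character(0)
  list(
    retained = `rownames<-`(events[!dropped, , drop = FALSE], NULL),
    dropped = `rownames<-`(drop_tab, NULL),
    tally = tally
  )
}

matches_polymorphic <- function(events, polymorphic, config) {
  if (nrow(events) == 0) return(logical(0))
  if (nrow(polymorphic) == 0) return(rep(FALSE, nrow(events)))
  if (config$polymorphic_mode == "reciprocal_overlap") {
    vapply(seq_len(nrow(events)), function(i) {
      sel <- polymorphic$chrom == events$chrom[i]
      if (!any(sel)) return(FALSE)
      ov <- pmin(events$end[i], polymorphic$end[sel]) -
        pmax(events$start[i], polymorphic$start[sel])
      ov <- pmax(ov, 0)
      size_e <- events$end[i] - events$start[i]
      size_p <- polymorphic$end[sel] - polymorphic$start[sel]
      any(ov / size_e >= config$polymorphic_identity &
            ov / size_p >= config$polymorphic_identity)
    }, logical(1))
  } else {
    vapply(seq_len(nrow(events)), function(i) {
      sel <- polymorphic$chrom == events$chrom[i]
      if (!any(sel)) return(FALSE)
      any(abs(events$start[i] - polymorphic$start[sel]) <= config$control_pad &
            abs(events$end[i] - polymorphic$end[sel]) <= config$control_pad)
    }, logical(1))
  }
}

#' Run the full WGS deletion-calling chain for one tumour sample
#'
#' Extraction, read-level filtering, deduplication and the filter cascade,
#' with control events and control coverage derived from the pooled
#' control segment tables.
#'
#' @param tumor_segments segment table of the tumour sample
#' @param control_segments list of control segment tables (pooled for
#'   breakpoint and coverage filters)
#' @param polymorphic,repeats interval tables (may be empty)
#' @param seqlengths named chromosome lengths (for coverage)
#' @param sample sample identifier
#' @param config a [wgs_config()]
#' @return list with `retained`, `dropped`, `tally`, `insertions` (side
#'   channel of insertion observations) and `control_events`
#' @export
call_wgs_sample <- function(tumor_segments, control_segments, polymorphic,
                            repeats, seqlengths, sample = "tumor",
                            config = wgs_config()) {
  obs <- extract_candidate_indels(tumor_segments, max_gap = config$max_size)
  kept <- filter_read_level(obs$deletions, config)
  events <- deduplicate_and_combine(kept, sample = sample)

  ctrl_all <- do.call(rbind, lapply(seq_along(control_segments), function(i) {
    cobs <- extract_candidate_indels(control_segments[[i]], max_gap = config$max_size)
    ckept <- filter_read_level(cobs$deletions, config)
    deduplicate_and_combine(ckept, sample = paste0("control", i))
  }))
  pooled_ctrl_segments <- do.call(rbind, control_segments)
  cov <- compute_coverage(pooled_ctrl_segments, seqlengths)

  res <- filter_deletions(events, ctrl_all, polymorphic, repeats, cov, config)
  res$insertions <- obs$insertions
  res$control_events <- ctrl_all
  res
}

#' Classify the frameshift consequence of a deletion
#'
#' The deletion size within the exon decides the outcome: no overlap means
#' no coding consequence; an exonic loss of 3N bases is in-frame; 3N+1 or
#' 3N+2 is a frameshift.
#'
#' @param events event table (or single event row)
#' @param exon list/row with `chrom`, `start`, `end` (0-based half-open)
#' @return character vector in
#'   `c("no_coding_overlap", "in_frame", "frameshift")`
#' @export
classify_frameshift <- function(events, exon) {
  d <- pmax(0, pmin(events$end, exon$end) - pmax(events$start, exon$start))
  d[events$chrom != exon$chrom] <- 0
  ifelse(d == 0, "no_coding_overlap",
         ifelse(d %% 3 == 0, "in_frame", "frameshift"))
}

#' Allele fractions at the targeted locus
#'
#' Classifies every read end overlapping the cut position (± `flank`) as
#' supporting one of the identified locus deletions (via its own deletion
#' observation exactly matching that event), as wild type (a contiguous
#' mapping stretch across the cut position), or as unassigned. Event
#' support is rolled up by frameshift consequence against the supplied
#' exon. This read-assignment step stands in for re-aligning all reads to
#' an indel-resolved reference set: with alignments already in hand, exact
#' breakpoint matching gives the same per-read labels at desk scale.
#'
#' @param segments segment table restricted to (or containing) the locus
#' @param locus_events event table of deletions at the locus (post-filter)
#' @param exon exon interval (`chrom`, `start`, `end`)
#' @param cut_pos 0-based cut position on the reference
#' @param flank half-width of the assignment window around `cut_pos`
#' @return list with `fractions` (named: wt, frameshift, in_frame),
#'   `counts` (including unassigned) and `n_assigned`; all-NA fractions
#'   when no read is assigned
#' @export
allele_fractions_at_locus <- function(segments, locus_events, exon, cut_pos,
                                      flank = 30L) {
  if (nrow(segments) == 0) {
    return(list(fractions = c(wt = NA_real_, frameshift = NA_real_, in_frame = NA_real_),
                counts = c(wt = 0L, frameshift = 0L, in_frame = 0L, unassigned = 0L),
                n_assigned = 0L))
  }
  cls <- if (nrow(locus_events)) classify_frameshift(locus_events, exon) else character(0)
  ev_key <- paste(locus_events$chrom, locus_events$start, locus_events$end)

  obs <- extract_candidate_indels(segments)$deletions
  obs_by_read <- split(obs, obs$read_id)

  cg <- parse_cigars(segments)
  win_lo <- cut_pos - flank
  win_hi <- cut_pos + flank

  counts <- c(wt = 0L, frameshift = 0L, in_frame = 0L, unassigned = 0L)
  for (id in unique(segments$read_id)) {
    idx <- which(segments$read_id == id)
    # reference span of the read end across its segments
    spans <- vapply(idx, function(i) {
      sum(cg$lens[[i]][cg$ops[[i]] %in% c("M", "D")])
    }, numeric(1))
    lo <- min(segments$pos[idx])
    hi <- max(segments$pos[idx] + spans)
    if (hi <= win_lo || lo >= win_hi) next  # does not overlap the window

    ro <- obs_by_read[[id]]
    if (!is.null(ro) && nrow(ro)) {
      keys <- paste(ro$chrom, ro$start, ro$end)
      hit <- match(keys, ev_key)
      hit <- hit[!is.na(hit)]
      if (length(hit)) {
        counts[cls[hit[1]]] <- counts[cls[hit[1]]] + 1L
        next
      }
      counts["unassigned"] <- counts["unassigned"] + 1L
      next
    }
    # wild type: one M run covering both bases flanking the cut
    is_wt <- FALSE
    for (i in idx) {
      rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        segments$cigar[i], ops = "M", pos = segments$pos[i] + 1L
      )[[1]]
      # M run covering 0-based positions [cut_pos - 1, cut_pos]
      if (any(IRanges::start(rr) <= cut_pos & IRanges::end(rr) >= cut_pos + 1L)) {
        is_wt <- TRUE
        break
      }
    }
    if (is_wt) counts["wt"] <- counts["wt"] + 1L
    else counts["unassigned"] <- counts["unassigned"] + 1L
  }
  n_assigned <- sum(counts[c("wt", "frameshift", "in_frame")])
  fractions <- if (n_assigned == 0) {
    c(wt = NA_real_, frameshift = NA_real_, in_frame = NA_real_)
  } else {
    counts[c("wt", "frameshift", "in_frame")] / n_assigned
  }
  list(fractions = fractions, counts = counts, n_assigned = as.integer(n_assigned))
}
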