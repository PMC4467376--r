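# File-format plumbing: BED interval tracks (via rtracklayer), minimal
# VCF 4.2 output, SAM text output for simulated alignments, TSV/JSON
# result writers. Internal coordinates are 0-based half-open; BED shares
# that convention, VCF and SAM are 1-based on output.

#' Read a BED track into a 0-based interval table
#'
#' @param path path to a BED file
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and, when present, `name`
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(gr$name)) out$name <- gr$name
  out
}

#' Write a 0-based interval table as BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optional
#'   `name`, `score` columns
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(intervals, path) {
  cols <- list(intervals$chrom, intervals$start, intervals$end)
  if (!is.null(intervals$name)) {
    cols <- c(cols, list(intervals$name))
    if (!is.null(intervals$score)) cols <- c(cols, list(intervals$score))
  }
  tab <- do.call(data.frame, c(cols, stringsAsFactors = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write amplicon indel calls as TSV
#'
#' @param calls call table from [call_indels()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_calls_tsv <- function(calls, path) {
  flat <- calls[, c("amplicons", "ref_start", "ref_span", "alt_seq", "length",
                    "n_amplicons", "max_fraction", "mean_fraction")]
  frs <- vapply(calls$fractions, function(fr) {
    paste(sprintf("%s=%.6g", names(fr), fr), collapse = ";")
  }, character(1))
  flat$per_amplicon_fraction <- if (length(frs)) frs else character(0)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write amplicon indel calls as minimal VCF 4.2
#'
#' Left-aligned, anchor-base representation: a deletion of span L at
#' 0-based `ref_start` s becomes POS = s (1-based position of the anchor
#' base at s-1), REF = anchor plus affected bases, ALT = anchor plus
#' alternative sequence.
#'
#' @param calls call table from [call_indels()]
#' @param locus_seq reference locus sequence (locus coordinates)
#' @param chrom chromosome name written to the VCF
#' @param path output path
#' @return `path`, invisibly
#' @export
write_calls_vcf <- function(calls, locus_seq, chrom, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, nchar(locus_seq)),
    "##INFO=<ID=INDELLEN,Number=1,Type=Integer,Description=\"Affected reference length minus alternative length\">",
    "##INFO=<ID=MAXFRAC,Number=1,Type=Float,Description=\"Maximum per-amplicon read fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  rows <- vapply(seq_len(nrow(calls)), function(i) {
    s <- calls$ref_start[i]
    span <- calls$ref_span[i]
    stopifnot(s >= 1)  # anchor base must exist
    anchor <- substr0(locus_seq, s - 1L, s)
    ref <- paste0(anchor, substr0(locus_seq, s, s + span))
    alt <- paste0(anchor, calls$alt_seq[i])
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tINDELLEN=%d;MAXFRAC=%.6g",
            chrom, s, ref, alt, calls$length[i], calls$max_fraction[i])
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write WGS deletion events as symbolic-allele VCF 4.2
#'
#' @param events event table (`chrom`, `start`, `end`, `support`)
#' @param genome named character vector of chromosome sequences (for the
#'   anchor base and contig lengths)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_deletions_vcf <- function(events, genome, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"1-based inclusive end\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Distinct supporting reads\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  rows <- vapply(seq_len(nrow(events)), function(i) {
    s <- events$start[i]
    stopifnot(s >= 1)
    anchor <- substr0(genome[[events$chrom[i]]], s - 1L, s)
    sprintf("%s\t%d\t.\t%s\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=%d;SUPPORT=%d",
            events$chrom[i], s, anchor, events$end[i], events$support[i])
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a segment table as SAM
#'
#' Emits a valid coordinate-sorted SAM with @HD/@SQ header, suitable for
#' re-reading with [read_alignment_segments()] (or any SAM consumer).
#'
#' @param segments segment table from [simulate_wgs_alignments()]
#' @param seqlengths named integer vector of chromosome lengths
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sam <- function(segments, seqlengths, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), as.integer(seqlengths))
  )
  if (nrow(segments) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  segments <- segments[order(segments$chrom, segments$pos), , drop = FALSE]
  flag <- rep(1L, nrow(segments))  # paired
  flag <- flag + ifelse(segments$strand == "-", 16L, 0L) +
    ifelse(segments$strand == "-", 0L, 32L) +  # mate on opposite strand
    ifelse(segments$mate == 1L, 64L, 128L) +
    ifelse(segments$is_supplementary, 2048L, 0L)
  rows <- sprintf(
    "%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t0\t%s\t%s",
    segments$qname, flag, segments$chrom, segments$pos + 1L,
    segments$cigar,
    ifelse(is.na(segments$mate_pos), "*", "="),
    ifelse(is.na(segments$mate_pos), 0L, segments$mate_pos + 1L),
    segments$seq, segments$qual
  )
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a clonality summary (or any result list) as JSON
#'
#' @param x a list (e.g. from [clonality_summary()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_json_summary <- function(x, path) {
  listify <- function(v) {
    if (is.list(v)) lapply(v, listify)
    else if (!is.null(names(v)) && length(v) > 1) as.list(v)
    else v
  }
  jsonlite::write_json(listify(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
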