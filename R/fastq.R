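# Paired FASTQ handling. Pairs are held as a plain data.frame with columns
# id, seq1, qual1, seq2, qual2; file IO goes through Biostrings (gzip
# transparent).

#' Read paired FASTQ files into a pair table
#'
#' @param r1,r2 paths to the forward and reverse FASTQ files (optionally
#'   gzipped). Records are paired by position; a mismatch in record count
#'   is an error naming both files.
#' @return data.frame with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`
#' @export
read_fastq_pairs <- function(r1, r2) {
  f <- tryCatch(
    Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ '", r1, "': ", conditionMessage(e))
  )
  r <- tryCatch(
    Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ '", r2, "': ", conditionMessage(e))
  )
  if (length(f) != length(r)) {
    stop("paired FASTQ files differ in record count: ", r1, " vs ", r2)
  }
  data.frame(
    id = sub(" .*", "", names(f)),
    seq1 = as.character(f),
    qual1 = as.character(S4Vectors::mcols(f)$qualities),
    seq2 = as.character(r),
    qual2 = as.character(S4Vectors::mcols(r)$qualities),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write a pair table as two FASTQ files
#'
#' @param pairs a pair table as returned by [read_fastq_pairs()]
#' @param r1,r2 output paths; a `.gz` suffix triggers gzip compression
#' @return `c(r1, r2)`, invisibly
#' @export
write_fastq_pairs <- function(pairs, r1, r2) {
  write_one <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(quals),
      compress = endsWith(path, ".gz")
    )
  }
  write_one(pairs$seq1, pairs$qual1, pairs$id, r1)
  write_one(pairs$seq2, pairs$qual2, pairs$id, r2)
  invisible(c(r1, r2))
}
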