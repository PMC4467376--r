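# Small DNA/string helpers shared across modules. Sequences are plain
# uppercase character vectors; coordinates are 0-based half-open unless a
# file format dictates otherwise (1-based POS in VCF/SAM).

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_dna <- function(x) {
  all(grepl("^[ACGT]+$", x))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @noRd
substr0 <- function(x, start0, end0) {
  # 0-based half-open substring
  substr(x, start0 + 1L, end0)
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Replace locus bases at a 0-based offset with `insert`
overwrite_at <- function(seq, offset0, insert) {
  stopifnot(offset0 + nchar(insert) <= nchar(seq))
  paste0(
    substr(seq, 1L, offset0),
    insert,
    substr(seq, offset0 + nchar(insert) + 1L, nchar(seq))
  )
}

#' Read a single-sequence or multi-sequence FASTA into a named character vector
#' @param path path to a FASTA file
#' @return named character vector of uppercase sequences
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
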