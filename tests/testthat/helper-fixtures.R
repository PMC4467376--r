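# Fixture builders used across test files. Everything is generated in
# code; seeds are fixed by the calling test.

rc_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# A two-amplicon panel over a shared random locus, both amplicons spanning
# positions [60, 140) of the locus.
tiny_panel <- function(locus_len = 200L) {
  locus <- rand_dna(locus_len)
  make_amp <- function(name, a0, a1) {
    ref <- substring(locus, a0 + 1, a1)
    list(name = name,
         fwd = substring(ref, 1, 10),
         rev = rc_chr(substring(ref, nchar(ref) - 9, nchar(ref))),
         a0 = a0, a1 = a1, ref = ref)
  }
  a <- make_amp("ampA", 0L, 150L)
  b <- make_amp("ampB", 30L, 180L)
  panel <- amplicon_panel(
    c(a$name, b$name), c(a$fwd, b$fwd), c(a$rev, b$rev),
    c(a$ref, b$ref), c(a$a0, b$a0)
  )
  list(locus = locus, panel = panel)
}

# Apply a deletion/insertion to a locus substring (0-based, locus coords)
edit_seq <- function(seq, del_start, del_end, insert = "") {
  paste0(substring(seq, 1, del_start), insert,
         substring(seq, del_end + 1, nchar(seq)))
}

# Alignment segment row(s) for WGS tests
make_seg <- function(read_id, pos, cigar, chrom = "chr1", strand = "+",
                     supp = FALSE, mate_pos = NA_integer_) {
  data.frame(read_id = read_id, chrom = chrom, pos = as.integer(pos),
             cigar = cigar, strand = strand, is_supplementary = supp,
             mate_pos = as.integer(mate_pos), stringsAsFactors = FALSE)
}

# Pair table row(s)
make_pairs <- function(seq1, seq2, qual1 = NULL, qual2 = NULL, id = NULL) {
  n <- length(seq1)
  if (n == 0) {
    return(data.frame(id = character(0), seq1 = character(0),
                      qual1 = character(0), seq2 = character(0),
                      qual2 = character(0), stringsAsFactors = FALSE))
  }
  if (is.null(qual1)) qual1 <- strrep("F", nchar(seq1))
  if (is.null(qual2)) qual2 <- strrep("F", nchar(seq2))
  if (is.null(id)) id <- paste0("read", seq_len(n))
  data.frame(id = id, seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2,
             stringsAsFactors = FALSE)
}

sort_by_size <- function(df) df[order(df$end - df$start), , drop = FALSE]

# Minimal amplicon-like record accepted by annotate_indels()
bare_amplicon <- function(ref, offset = 0L, name = "amp") {
  data.frame(name = name, fwd_primer = "A", rev_primer = "A",
             ref_seq = ref, ref_offset = as.integer(offset),
             stringsAsFactors = FALSE)
}
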