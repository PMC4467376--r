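#' Construct and validate an amplicon panel
#'
#' An amplicon panel describes the staggered PCR products tiled across a
#' target locus. Each amplicon carries its primer pair, its full expected
#' (wild-type) sequence in forward orientation, and the 0-based offset of
#' that sequence on the locus.
#'
#' @param name character vector of amplicon identifiers (unique)
#' @param fwd_primer,rev_primer uppercase A/C/G/T primer sequences; the
#'   reverse primer is given in its own (reverse-read) orientation, so
#'   `ref_seq` must end with its reverse complement
#' @param ref_seq full expected amplicon sequence, forward orientation
#' @param ref_offset integer >= 0, 0-based start of `ref_seq` on the locus
#' @return a `data.frame` of class `amplicon_panel`
#' @export
amplicon_panel <- function(name, fwd_primer, rev_primer, ref_seq, ref_offset) {
  panel <- data.frame(
    name = as.character(name),
    fwd_primer = toupper(fwd_primer),
    rev_primer = toupper(rev_primer),
    ref_seq = toupper(ref_seq),
    ref_offset = as.integer(ref_offset),
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
  class(panel) <- c("amplicon_panel", "data.frame")
  panel
}

validate_panel <- function(panel) {
  if (anyDuplicated(panel$name)) {
    stop("amplicon names must be unique")
  }
  if (!all(nzchar(panel$fwd_primer)) || !all(nzchar(panel$rev_primer))) {
    stop("primers must be non-empty")
  }
  if (!is_dna(panel$fwd_primer) || !is_dna(panel$rev_primer)) {
    stop("primers must be uppercase A/C/G/T only")
  }
  if (any(panel$ref_offset < 0)) stop("ref_offset must be >= 0")
  key <- paste(panel$fwd_primer, panel$rev_primer)
  if (anyDuplicated(key)) {
    stop("two amplicons share an identical primer pair; reads cannot be demultiplexed")
  }
  ok_start <- startsWith(panel$ref_seq, panel$fwd_primer)
  ok_end <- endsWith(panel$ref_seq, revcomp(panel$rev_primer))
  if (!all(ok_start)) {
    stop("ref_seq must begin with fwd_primer: ", paste(panel$name[!ok_start], collapse = ", "))
  }
  if (!all(ok_end)) {
    stop("ref_seq must end with reverse complement of rev_primer: ",
         paste(panel$name[!ok_end], collapse = ", "))
  }
  invisible(panel)
}

#' Read an amplicon panel from a TSV plus a locus FASTA
#'
#' The TSV carries columns `name`, `fwd_primer`, `rev_primer` and
#' optionally `ref_offset`. Each amplicon's reference sequence is located
#' on the locus: the forward primer must occur at `ref_offset` (or, when
#' `ref_offset` is absent, at its unique match on the locus) and the
#' amplicon extends to the end of the first downstream occurrence of the
#' reverse complement of the reverse primer.
#'
#' @param panel_tsv path to the panel TSV
#' @param locus either a path to a FASTA file or a single locus sequence
#' @return an `amplicon_panel`
#' @export
read_panel <- function(panel_tsv, locus) {
  tab <- utils::read.delim(panel_tsv, stringsAsFactors = FALSE)
  req <- c("name", "fwd_primer", "rev_primer")
  if (!all(req %in% names(tab))) {
    stop("panel TSV must have columns: ", paste(req, collapse = ", "))
  }
  if (length(locus) == 1 && file.exists(locus)) {
    locus <- unname(read_genome_fasta(locus)[1])
  }
  locus <- toupper(locus)
  offsets <- integer(nrow(tab))
  ref_seqs <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    fwd <- toupper(tab$fwd_primer[i])
    rev_rc <- revcomp(toupper(tab$rev_primer[i]))
    if (!is.null(tab$ref_offset)) {
      off <- as.integer(tab$ref_offset[i])
      if (substr0(locus, off, off + nchar(fwd)) != fwd) {
        stop("forward primer of '", tab$name[i], "' not found at ref_offset ", off)
      }
    } else {
      hit <- gregexpr(fwd, locus, fixed = TRUE)[[1]]
      if (hit[1] < 0 || length(hit) != 1) {
        stop("forward primer of '", tab$name[i], "' has no unique match on the locus")
      }
      off <- hit[1] - 1L
    }
    down <- substr(locus, off + 1L, nchar(locus))
    rhit <- regexpr(rev_rc, down, fixed = TRUE)
    if (rhit < 0) {
      stop("reverse primer of '", tab$name[i], "' not found downstream of its forward primer")
    }
    end0 <- off + (rhit - 1L) + nchar(rev_rc)
    offsets[i] <- off
    ref_seqs[i] <- substr0(locus, off, end0)
  }
  amplicon_panel(tab$name, tab$fwd_primer, tab$rev_primer, ref_seqs, offsets)
}

#' Primer pairs of the five staggered Ptch1 amplicons
#'
#' The five consecutively shifted primer pairs used for targeted deep
#' sequencing of the Ptch1 target locus, shipped as a package fixture.
#'
#' @return data.frame with columns `name`, `fwd_primer`, `rev_primer`
#' @export
ptch1_primers <- function() {
  utils::read.delim(
    system.file("extdata", "ptch1_staggered_primers.tsv", package = "editcall"),
    stringsAsFactors = FALSE
  )
}

#' Guide RNA protospacers targeting Ptch1, Nf1, Pten and Trp53
#'
#' The 20-mer protospacers (three Ptch1 guides, the Nf1/Pten/Trp53 guides
#' and the non-targeting control guide gNT), shipped as a fixture.
#'
#' @return data.frame with columns `name`, `protospacer`
#' @export
crispr_guides <- function() {
  utils::read.delim(
    system.file("extdata", "guides.tsv", package = "editcall"),
    stringsAsFactors = FALSE
  )
}
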