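#' Configuration for the amplicon indel caller
#'
#' Thresholds and scoring used by the demultiplex / merge / collapse /
#' annotate / call chain. Defaults follow the published procedure for
#' staggered-amplicon deep sequencing of an edited locus: singleton-like
#' fragments (< 100 copies) are discarded, and an indel is called when it is
#' supported by at least 0.5% of merged reads in at least two amplicons.
#'
#' @param min_fragment_count collapse filter: fragments occurring fewer than
#'   this many times are removed (strict `<`; a fragment at exactly the
#'   threshold is retained). Default 100.
#' @param min_fraction minimum per-amplicon read fraction for an indel to
#'   count as supported in that amplicon (inclusive). Default 0.005.
#' @param min_amplicons minimum number of supporting amplicons (inclusive).
#'   Default 2.
#' @param min_indel_len_for_clonality clonality summaries count indels with
#'   `abs(length)` strictly greater than this. Default 1 (i.e. "> 1 bp").
#' @param min_merge_overlap minimum mate overlap accepted when merging.
#' @param max_merge_mismatch_frac maximum mismatch fraction inside the
#'   overlap.
#' @param match,mismatch,gap_open,gap_extend global-alignment scoring used
#'   to annotate indels. The defaults (+2/-4/-6/-1) favour one consolidated
#'   gap over scattered small gaps, matching the single-deletion events that
#'   dominate Cas9 repair outcomes.
#' @param denominator whether per-amplicon read fractions divide by the
#'   merged read count after (`"post_filter"`, default) or before
#'   (`"pre_filter"`) the `< min_fragment_count` fragment filter. The
#'   post-filter denominator makes fractions robust to sequencing error:
#'   reads carrying a random substitution leave both numerator and
#'   denominator at the same allele-independent rate, so allele fractions
#'   are unbiased, whereas a pre-filter denominator deflates every
#'   fraction by the per-fragment error probability (roughly
#'   `exp(-error_rate * fragment_length)`, a third at 0.1% error on a
#'   420 bp fragment).
#' @param per_amplicon_fraction if `TRUE` (default) an indel must reach
#'   `min_fraction` in each of `min_amplicons` amplicons; if `FALSE` it must
#'   be present in `min_amplicons` amplicons and reach `min_fraction`
#'   pooled over all amplicons.
#' @return a list of class `caller_config`
#' @export
caller_config <- function(min_fragment_count = 100L,
                          min_fraction = 0.005,
                          min_amplicons = 2L,
                          min_indel_len_for_clonality = 1L,
                          min_merge_overlap = 10L,
                          max_merge_mismatch_frac = 0.1,
                          match = 2, mismatch = -4,
                          gap_open = -6, gap_extend = -1,
                          denominator = c("post_filter", "pre_filter"),
                          per_amplicon_fraction = TRUE) {
  denominator <- match.arg(denominator)
  stopifnot(
    min_fragment_count >= 0, min_amplicons >= 1,
    min_fraction > 0, min_fraction < 1,
    min_merge_overlap >= 1,
    max_merge_mismatch_frac >= 0, max_merge_mismatch_frac < 1,
    min_indel_len_for_clonality >= 0
  )
  structure(list(
    min_fragment_count = as.integer(min_fragment_count),
    min_fraction = min_fraction,
    min_amplicons = as.integer(min_amplicons),
    min_indel_len_for_clonality = as.integer(min_indel_len_for_clonality),
    min_merge_overlap = as.integer(min_merge_overlap),
    max_merge_mismatch_frac = max_merge_mismatch_frac,
    match = match, mismatch = mismatch,
    gap_open = gap_open, gap_extend = gap_extend,
    denominator = denominator,
    per_amplicon_fraction = isTRUE(per_amplicon_fraction)
  ), class = "caller_config")
}

#' Configuration for the WGS deletion filter cascade
#'
#' @param min_stretch minimum size (bp) of every mapping stretch (CIGAR M
#'   run) of a read contributing a deletion observation. Default 25.
#' @param min_mapped_total minimum total mapped bases of such a read.
#'   Default 95.
#' @param min_size,max_size retained deletion size range, inclusive
#'   (default 4 bp to 100 kb).
#' @param control_pad breakpoint padding (bp) when matching against control
#'   breakpoints and repeat intervals. Default 5.
#' @param polymorphic_identity reciprocal-overlap fraction above which an
#'   event is considered identical to a known polymorphic indel (strict
#'   `>=` on the reciprocal overlap, mirroring "> 80% identity").
#'   Default 0.80.
#' @param max_control_coverage breakpoints in regions whose combined
#'   control coverage strictly exceeds this are filtered (250 kept,
#'   251 dropped). Default 250.
#' @param polymorphic_mode `"reciprocal_overlap"` (default) compares event
#'   and track intervals by reciprocal overlap; `"breakpoint"` instead
#'   drops events whose breakpoints both fall within `control_pad` of a
#'   polymorphic interval's breakpoints.
#' @return a list of class `wgs_config`
#' @export
wgs_config <- function(min_stretch = 25L,
                       min_mapped_total = 95L,
                       min_size = 4L,
                       max_size = 100000L,
                       control_pad = 5L,
                       polymorphic_identity = 0.80,
                       max_control_coverage = 250L,
                       polymorphic_mode = c("reciprocal_overlap", "breakpoint")) {
  polymorphic_mode <- match.arg(polymorphic_mode)
  stopifnot(
    min_stretch >= 0, min_mapped_total >= 0,
    min_size >= 0, max_size >= min_size, control_pad >= 0,
    polymorphic_identity > 0, polymorphic_identity <= 1,
    max_control_coverage >= 0
  )
  structure(list(
    min_stretch = as.integer(min_stretch),
    min_mapped_total = as.integer(min_mapped_total),
    min_size = as.integer(min_size),
    max_size = as.integer(max_size),
    control_pad = as.integer(control_pad),
    polymorphic_identity = polymorphic_identity,
    max_control_coverage = as.integer(max_control_coverage),
    polymorphic_mode = polymorphic_mode
  ), class = "wgs_config")
}
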