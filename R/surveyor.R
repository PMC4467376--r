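# SURVEYOR nuclease assay quantification. Band intensities come from gel
# densitometry (e.g. ImageJ); this module turns them into a cleaved
# fraction and a percent-modified estimate.

#' Fraction of cleaved product from band intensities
#'
#' After per-band background subtraction (floored at 0), the cleaved
#' fraction is the summed cleavage-product intensity over the total
#' intensity — the standard SURVEYOR convention:
#' `sum(cleaved) / (sum(cleaved) + parent)`.
#'
#' @param parent intensity of the uncleaved parental band
#' @param cleaved numeric vector of cleavage-product band intensities
#'   (may be empty)
#' @param background per-band background intensity, subtracted from every
#'   band (default 0)
#' @return cleaved fraction in `[0, 1]`
#' @export
fraction_cleaved <- function(parent, cleaved = numeric(0), background = 0) {
  if (parent < 0 || any(cleaved < 0) || background < 0) {
    stop("band intensities must be non-negative")
  }
  parent <- max(parent - background, 0)
  cleaved <- pmax(cleaved - background, 0)
  total <- parent + sum(cleaved)
  if (total == 0) {
    stop("all bands are zero after background subtraction")
  }
  sum(cleaved) / total
}

#' Percent of alleles modified from the cleaved fraction
#'
#' The heteroduplex formed by re-annealing a mixed pool is cleaved when
#' the two strands differ, so the cleaved fraction relates quadratically
#' to the modified-allele fraction:
#' `% modified = (1 - sqrt(1 - fraction_cleaved)) * 100`.
#'
#' @param fc cleaved fraction(s) in `[0, 1]`
#' @return percentage(s) in `[0, 100]`, strictly increasing in `fc`
#' @export
percent_modified <- function(fc) {
  if (any(is.na(fc)) || any(fc < 0 | fc > 1)) {
    stop("fraction cleaved must lie in [0, 1]")
  }
  (1 - sqrt(1 - fc)) * 100
}

#' Quantify a table of SURVEYOR lanes
#'
#' @param table data.frame (or TSV path) with columns `lane`, `parent`,
#'   one or more `cleaved*` columns, and optionally `background`
#' @return the table with added `fraction_cleaved` and `percent_modified`
#'   columns
#' @export
surveyor_table <- function(table) {
  if (is.character(table)) table <- utils::read.delim(table, stringsAsFactors = FALSE)
  cleaved_cols <- grep("^cleaved", names(table), value = TRUE)
  if (!("parent" %in% names(table)) || length(cleaved_cols) == 0) {
    stop("table needs a 'parent' column and at least one 'cleaved*' column")
  }
  bg <- if ("background" %in% names(table)) table$background else rep(0, nrow(table))
  fc <- vapply(seq_len(nrow(table)), function(i) {
    cl <- as.numeric(table[i, cleaved_cols])
    fraction_cleaved(table$parent[i], cl[!is.na(cl)], bg[i])
  }, numeric(1))
  table$fraction_cleaved <- fc
  table$percent_modified <- percent_modified(fc)
  table
}
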