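# Seeded synthetic-data generator emulating polyclonal CRISPR-edited
# tumour sequencing: a surrogate target locus with the real guide
# protospacer and the five staggered amplicon primer pairs planted in
# random sequence, clone populations with ground-truth edits, amplicon
# paired reads, WGS alignment records (tumour + matched control) and
# annotation tracks.

#' Simulation configuration
#'
#' Defaults mirror the study's sequencing design: 251 bp paired-end
#' amplicon reads at very high depth, 101 bp paired-end WGS at 23.3-fold
#' mean coverage, and a 0.1% per-base substitution error rate.
#'
#' @param seed integer seed; a fixed seed makes every generator output
#'   byte-identical
#' @param n_pairs_per_amplicon read pairs simulated per amplicon
#' @param read_len amplicon read length (bp)
#' @param wgs_read_len WGS read length (bp)
#' @param wgs_depth mean WGS coverage
#' @param error_rate per-base substitution probability
#' @param n_background_clones number of rare background clones in
#'   polyclonal populations
#' @param split_threshold deletions larger than this many bp are emitted
#'   as split alignment segments rather than a CIGAR D run, mimicking how
#'   aligners represent large deletions
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_pairs_per_amplicon = 50000L,
                       read_len = 251L,
                       wgs_read_len = 101L,
                       wgs_depth = 23.3,
                       error_rate = 0.001,
                       n_background_clones = 20L,
                       split_threshold = 50L) {
  stopifnot(read_len > 0, wgs_read_len > 0, wgs_depth >= 0,
            error_rate >= 0, error_rate < 1, n_background_clones >= 0)
  structure(list(
    seed = as.integer(seed),
    n_pairs_per_amplicon = as.integer(n_pairs_per_amplicon),
    read_len = as.integer(read_len),
    wgs_read_len = as.integer(wgs_read_len),
    wgs_depth = wgs_depth,
    error_rate = error_rate,
    n_background_clones = as.integer(n_background_clones),
    split_threshold = as.integer(split_threshold)
  ), class = "sim_config")
}

#' Build a surrogate target locus and amplicon panel
#'
#' Generates a random locus, plants the guide protospacer (default: the
#' Ptch1.1 guide) so that the blunt Cas9 cut falls at `cut_pos` (3 bp 5'
#' of the PAM, which is planted as TGG), and plants the five staggered
#' primer pairs so that every amplicon spans the cut site. Uses the
#' current RNG state; seed beforehand for reproducibility.
#'
#' @param locus_len locus length in bp (default 3000)
#' @param cut_pos 0-based cut position (default 1500)
#' @param guide 20-mer protospacer to plant
#' @param primers data.frame of primer pairs (default [ptch1_primers()])
#' @param amp_len amplicon length (default 420)
#' @param stagger offset between consecutive amplicon starts (default 45)
#' @param chrom chromosome name of the surrogate locus
#' @return list with `locus_seq`, `cut_pos`, `chrom`, `guide`, `panel`
#'   (an [amplicon_panel()])
#' @export
build_reference <- function(locus_len = 3000L, cut_pos = 1500L,
                            guide = NULL, primers = ptch1_primers(),
                            amp_len = 420L, stagger = 45L, chrom = "chrS") {
  if (is.null(guide)) {
    g <- crispr_guides()
    guide <- g$protospacer[g$name == "Ptch1.1"]
  }
  stopifnot(nchar(guide) == 20L)
  locus <- random_dna(locus_len)
  proto_start <- cut_pos - 17L
  stopifnot(proto_start >= 0, cut_pos + 6L <= locus_len)
  locus <- overwrite_at(locus, proto_start, paste0(guide, "TGG"))

  n_amp <- nrow(primers)
  starts <- cut_pos - (amp_len - 50L) + stagger * (seq_len(n_amp) - 1L)
  ends <- starts + amp_len
  stopifnot(all(starts >= 0), all(ends <= locus_len),
            all(starts < cut_pos - 40L), all(ends > cut_pos + 40L))
  for (i in seq_len(n_amp)) {
    fwd <- primers$fwd_primer[i]
    rev_rc <- revcomp(primers$rev_primer[i])
    # primer sites must not overwrite the protospacer/PAM
    stopifnot(starts[i] + nchar(fwd) <= proto_start,
              ends[i] - nchar(rev_rc) >= cut_pos + 6L)
    locus <- overwrite_at(locus, starts[i], fwd)
    locus <- overwrite_at(locus, ends[i] - nchar(rev_rc), rev_rc)
  }
  panel <- amplicon_panel(
    primers$name, primers$fwd_primer, primers$rev_primer,
    vapply(seq_len(n_amp), function(i) substr0(locus, starts[i], ends[i]), character(1)),
    starts
  )
  list(locus_seq = locus, cut_pos = as.integer(cut_pos), chrom = chrom,
       guide = guide, panel = panel)
}

#' Assemble a clone population
#'
#' A population is the generative ground truth: a list of edited alleles
#' (deletion interval plus optional inserted sequence) with cellular
#' frequencies; the remaining mass is wild type.
#'
#' @param reference a [build_reference()] result
#' @param clones data.frame with columns `del_start`, `del_end` (0-based
#'   half-open; equal for pure insertions), `insert_seq` ("" for pure
#'   deletions) and `freq`
#' @return list of class `clone_population`
#' @export
clone_population <- function(reference, clones) {
  if (nrow(clones) > 0) {
    stopifnot(all(clones$freq >= 0), all(clones$del_end >= clones$del_start))
    if (sum(clones$freq) > 1 + 1e-9) {
      stop("clone frequencies sum to more than 1")
    }
    near_cut <- clones$del_start <= reference$cut_pos + 20L &
      clones$del_end >= reference$cut_pos - 20L
    if (!all(near_cut)) stop("every edit must overlap the cut position +/- 20 bp")
  }
  clones$clone_id <- if (nrow(clones)) paste0("clone", seq_len(nrow(clones))) else character(0)
  structure(list(
    reference = reference,
    clones = clones,
    wt_freq = max(0, 1 - sum(clones$freq))
  ), class = "clone_population")
}

#' Simulate a polyclonal edited population
#'
#' Draws a population with `length(major_freqs)` predominant clones
#' carrying distinct frameshift deletions centred on the cut site, plus a
#' tail of rare background clones (small deletions, or insertions under
#' 10 bp) sharing `tail_mass` equally. Seeds the RNG from
#' `config$seed`.
#'
#' @param reference a [build_reference()] result
#' @param config a [sim_config()]
#' @param major_freqs frequencies of the predominant clones
#' @param tail_mass total frequency mass of the background clones
#' @param insert_prob probability that a background clone carries an
#'   insertion rather than a deletion
#' @return a [clone_population()]
#' @export
simulate_clones <- function(reference, config = sim_config(),
                            major_freqs = c(0.475, 0.285, 0.19),
                            tail_mass = 0.05,
                            insert_prob = 0.3) {
  set.seed(config$seed)
  if (sum(major_freqs) + tail_mass > 1 + 1e-9) {
    stop("clone frequencies sum to more than 1")
  }
  cut <- reference$cut_pos
  k <- length(major_freqs)
  # distinct frameshift deletions: sizes 5, 11, 17, ... (all = 2 mod 3)
  major_sizes <- 6L * seq_len(k) - 1L
  majors <- data.frame(
    del_start = cut - major_sizes %/% 2L,
    del_end = cut - major_sizes %/% 2L + major_sizes,
    insert_seq = "",
    freq = major_freqs,
    stringsAsFactors = FALSE
  )
  n_bg <- if (tail_mass > 0) config$n_background_clones else 0L
  tail <- if (n_bg > 0) {
    is_ins <- stats::runif(n_bg) < insert_prob
    del_size <- ifelse(is_ins, 0L, sample(1:30, n_bg, replace = TRUE))
    ins_len <- ifelse(is_ins, sample(1:9, n_bg, replace = TRUE), 0L)
    del_start <- ifelse(is_ins, cut,
                        cut - vapply(del_size, function(s) sample.int(max(s, 1L), 1L) - 1L,
                                     integer(1)))
    data.frame(
      del_start = del_start,
      del_end = del_start + del_size,
      insert_seq = vapply(ins_len, function(l) if (l > 0) random_dna(l) else "",
                          character(1)),
      freq = rep(tail_mass / n_bg, n_bg),
      stringsAsFactors = FALSE
    )
  } else {
    majors[0, ]
  }
  clones <- rbind(majors, tail)
  # collapse accidental duplicates of the same edit (keeps truth 1:1)
  key <- paste(clones$del_start, clones$del_end, clones$insert_seq)
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(freq ~ key, data = cbind(clones, key = key), FUN = sum)
    clones <- clones[!duplicated(key), , drop = FALSE]
    clones$freq <- agg$freq[match(paste(clones$del_start, clones$del_end,
                                        clones$insert_seq), agg$key)]
  }
  clone_population(reference, clones)
}

#' Preset populations
#'
#' \describe{
#'   \item{polyclonal-mb}{three predominant clones holding 95% of the
#'     cell mass at relative weights 0.5/0.3/0.2, a 20-clone background
#'     tail sharing 5%, no wild type — the polyclonal, biallelically
#'     disrupted tumour picture.}
#'   \item{biallelic-ko}{two clones at 0.5 each: a 10 bp frameshift
#'     deletion and a 1,435 bp deletion (the canonical large-deletion
#'     fixture), no wild type.}
#'   \item{control}{pure wild type.}
#' }
#'
#' @param preset preset name
#' @param config a [sim_config()]
#' @param reference optional [build_reference()]; built (seeded from
#'   `config$seed`) when absent
#' @return a [clone_population()]
#' @export
population_preset <- function(preset = c("polyclonal-mb", "biallelic-ko", "control"),
                              config = sim_config(), reference = NULL) {
  preset <- match.arg(preset)
  if (is.null(reference)) {
    set.seed(config$seed)
    reference <- build_reference()
  }
  cut <- reference$cut_pos
  switch(preset,
    "polyclonal-mb" = simulate_clones(
      reference, config,
      major_freqs = c(0.5, 0.3, 0.2) * 0.95, tail_mass = 0.05
    ),
    "biallelic-ko" = clone_population(reference, data.frame(
      del_start = c(cut - 5L, cut - 717L),
      del_end = c(cut + 5L, cut - 717L + 1435L),
      insert_seq = c("", ""),
      freq = c(0.5, 0.5),
      stringsAsFactors = FALSE
    )),
    "control" = clone_population(reference, data.frame(
      del_start = integer(0), del_end = integer(0),
      insert_seq = character(0), freq = numeric(0),
      stringsAsFactors = FALSE
    ))
  )
}

# Map a 0-based reference position to allele coordinates given one edit;
# NA inside a deleted interval.
map_ref_to_allele <- function(p, del_start, del_end, ins_len) {
  shift <- ins_len - (del_end - del_start)
  ifelse(p <= del_start, p, ifelse(p >= del_end, p + shift, NA_integer_))
}

apply_edit <- function(locus, del_start, del_end, insert_seq) {
  paste0(substr(locus, 1L, del_start), insert_seq,
         substr(locus, del_end + 1L, nchar(locus)))
}

#' Simulate paired amplicon reads from a clone population
#'
#' For each amplicon, read pairs are drawn clone-proportionally
#' (multinomial, seeded from `config$seed`); substitution errors are
#' applied at `config$error_rate` and constant Q37 qualities emitted.
#' Alleles whose edit disrupts a primer site yield no reads for that
#' amplicon; the remaining allele frequencies are renormalised (PCR
#' amplifies what can still prime) and the dropout is recorded in the
#' truth table.
#'
#' @param pop a [clone_population()]
#' @param config a [sim_config()]
#' @param sample sample name used in read ids
#' @return list with `pairs` (pair table, see [read_fastq_pairs()]) and
#'   `truth` (per clone x amplicon: canonical left-aligned indel
#'   representation, `expected_fraction`, `dropout`)
#' @export
simulate_amplicon_reads <- function(pop, config = sim_config(), sample = "tumor") {
  set.seed(config$seed + 1L)
  ref <- pop$reference
  panel <- ref$panel
  locus <- ref$locus_seq
  clones <- pop$clones
  n_cl <- nrow(clones)

  allele_seqs <- vapply(seq_len(n_cl), function(i) {
    apply_edit(locus, clones$del_start[i], clones$del_end[i], clones$insert_seq[i])
  }, character(1))

  canon <- lapply(seq_len(n_cl), function(i) {
    span <- clones$del_end[i] - clones$del_start[i]
    left_align_indel(locus, clones$del_start[i], span, clones$insert_seq[i])
  })

  all_pairs <- list()
  truth <- list()
  for (ai in seq_len(nrow(panel))) {
    a <- panel[ai, ]
    a0 <- a$ref_offset
    a1 <- a$ref_offset + nchar(a$ref_seq)
    lf <- nchar(a$fwd_primer)
    lr <- nchar(a$rev_primer)

    frag <- character(n_cl + 1L)
    drop <- logical(n_cl + 1L)
    frag[1] <- a$ref_seq  # wild type
    for (i in seq_len(n_cl)) {
      ds <- clones$del_start[i]; de <- clones$del_end[i]
      il <- nchar(clones$insert_seq[i])
      primer_hit <- (de > a0 && ds < a0 + lf) || (de > a1 - lr && ds < a1) ||
        (ds == de && il > 0 && (ds > a0 && ds < a0 + lf || ds > a1 - lr && ds < a1))
      m0 <- map_ref_to_allele(a0, ds, de, il)
      m1 <- map_ref_to_allele(a1, ds, de, il)
      if (primer_hit || is.na(m0) || is.na(m1)) {
        drop[i + 1L] <- TRUE
      } else {
        frag[i + 1L] <- substr0(allele_seqs[i], m0, m1)
      }
    }

    probs <- c(pop$wt_freq, clones$freq)
    probs[drop] <- 0
    if (sum(probs) == 0) {
      stop("no allele can amplify in amplicon '", a$name, "'")
    }
    probs <- probs / sum(probs)
    counts <- as.integer(stats::rmultinom(1, config$n_pairs_per_amplicon, probs))

    keep <- which(counts > 0 & !drop)
    rl <- config$read_len
    fwd_u <- vapply(keep, function(j) substr(frag[j], 1L, min(rl, nchar(frag[j]))),
                    character(1))
    rev_u <- vapply(keep, function(j) {
      n <- nchar(frag[j])
      revcomp(substr(frag[j], max(1L, n - rl + 1L), n))
    }, character(1))
    n_reads <- counts[keep]
    fwd <- rep(fwd_u, n_reads)
    rev <- rep(rev_u, n_reads)
    fwd <- cpp_mutate_seqs(fwd, stats::rbinom(length(fwd), nchar(fwd), config$error_rate))
    rev <- cpp_mutate_seqs(rev, stats::rbinom(length(rev), nchar(rev), config$error_rate))
    all_pairs[[ai]] <- data.frame(
      id = paste0(sample, ":", a$name, ":", seq_along(fwd)),
      seq1 = fwd, qual1 = strrep("F", nchar(fwd)),
      seq2 = rev, qual2 = strrep("F", nchar(rev)),
      stringsAsFactors = FALSE
    )

    if (n_cl > 0) {
      truth[[ai]] <- data.frame(
        clone_id = clones$clone_id,
        amplicon = a$name,
        ref_start = vapply(canon, function(x) x$start0, integer(1)),
        ref_span = vapply(canon, function(x) x$span, integer(1)),
        alt_seq = vapply(canon, function(x) x$alt, character(1)),
        length = vapply(canon, function(x) x$span - nchar(x$alt), integer(1)),
        freq = clones$freq,
        expected_fraction = probs[-1L],
        dropout = drop[-1L],
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    pairs = do.call(rbind, all_pairs),
    truth = if (length(truth)) do.call(rbind, truth) else NULL
  )
}

#' Simulate WGS alignment records from a clone population
#'
#' Read pairs are drawn allele-proportionally across the locus at
#' `config$wgs_depth`; each end is mapped back to reference coordinates.
#' Reads spanning a deletion no larger than `config$split_threshold` carry
#' a CIGAR D run; larger deletions are emitted as two split segments (the
#' shorter one flagged supplementary), as an aligner would. A control
#' sample contains only wild-type reads plus any planted polymorphic
#' deletions.
#'
#' @param pop a [clone_population()]
#' @param config a [sim_config()]
#' @param sample sample name (read name prefix)
#' @param control simulate a matched unedited control (somatic clones
#'   ignored)
#' @param planted_polymorphic optional data.frame (`del_start`, `del_end`,
#'   `freq`) of germline-like deletions present in this sample
#' @param seed RNG seed for this sample (default `config$seed + 2`);
#'   give each cohort sample its own seed
#' @return list with `segments` (segment table, see
#'   [read_alignment_segments()]) and `truth` (somatic deletion table;
#'   empty for controls)
#' @export
simulate_wgs_alignments <- function(pop, config = sim_config(), sample = "tumor",
                                    control = FALSE, planted_polymorphic = NULL,
                                    seed = config$seed + 2L) {
  set.seed(seed)
  ref <- pop$reference
  locus <- ref$locus_seq
  L <- nchar(locus)
  rl <- config$wgs_read_len

  if (control) {
    clones <- if (is.null(planted_polymorphic)) {
      data.frame(del_start = integer(0), del_end = integer(0),
                 insert_seq = character(0), freq = numeric(0))
    } else {
      data.frame(del_start = planted_polymorphic$del_start,
                 del_end = planted_polymorphic$del_end,
                 insert_seq = "", freq = planted_polymorphic$freq,
                 stringsAsFactors = FALSE)
    }
    wt_freq <- max(0, 1 - sum(clones$freq))
  } else {
    clones <- pop$clones[, c("del_start", "del_end", "insert_seq", "freq")]
    wt_freq <- pop$wt_freq
  }
  n_cl <- nrow(clones)
  allele_seqs <- c(locus, vapply(seq_len(n_cl), function(i) {
    apply_edit(locus, clones$del_start[i], clones$del_end[i], clones$insert_seq[i])
  }, character(1)))

  n_pairs <- round(config$wgs_depth * L / (2 * rl))
  truth <- if (!control && n_cl > 0) {
    dels <- clones[clones$del_end > clones$del_start, , drop = FALSE]
    data.frame(chrom = ref$chrom, start = dels$del_start, end = dels$del_end,
               size = dels$del_end - dels$del_start, freq = dels$freq,
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               size = integer(0), freq = numeric(0), stringsAsFactors = FALSE)
  }
  empty_seg <- data.frame(
    qname = character(0), mate = integer(0), read_id = character(0),
    chrom = character(0), pos = integer(0), cigar = character(0),
    strand = character(0), is_supplementary = logical(0),
    mate_pos = integer(0), seq = character(0), qual = character(0),
    stringsAsFactors = FALSE
  )
  if (n_pairs == 0) return(list(segments = empty_seg, truth = truth))

  probs <- c(wt_freq, clones$freq)
  if (sum(probs) <= 0) stop("allele frequencies sum to zero")
  alleles <- sample.int(n_cl + 1L, n_pairs, replace = TRUE, prob = probs)
  isize <- pmax(2L * rl + 10L, round(stats::rnorm(n_pairs, 350, 30)))

  segs <- list()
  for (i in seq_len(n_pairs)) {
    al <- alleles[i]
    aseq <- allele_seqs[al]
    La <- nchar(aseq)
    stopifnot(La >= rl)
    ins <- min(isize[i], La)
    u <- sample.int(La - ins + 1L, 1L) - 1L
    qname <- paste0(sample, ":", i)
    ends <- list(
      list(mate = 1L, s = u, strand = "+"),
      list(mate = 2L, s = u + ins - rl, strand = "-")
    )
    mate_starts <- c(NA_integer_, NA_integer_)
    rows <- list()
    for (e in ends) {
      er <- if (al == 1L) {
        plain_segment(e$s, rl)
      } else {
        edited_segments(e$s, rl, clones$del_start[al - 1L], clones$del_end[al - 1L],
                        nchar(clones$insert_seq[al - 1L]), config$split_threshold)
      }
      read_seq <- substr0(aseq, e$s, e$s + rl)
      read_seq <- cpp_mutate_seqs(read_seq, stats::rbinom(1L, rl, config$error_rate))
      for (k in seq_along(er$pos)) {
        rows[[length(rows) + 1L]] <- data.frame(
          qname = qname, mate = e$mate,
          read_id = paste0(qname, "/", e$mate),
          chrom = ref$chrom, pos = er$pos[k], cigar = er$cigar[k],
          strand = e$strand, is_supplementary = er$supp[k],
          mate_pos = NA_integer_, seq = read_seq,
          qual = strrep("F", rl), stringsAsFactors = FALSE
        )
      }
      mate_starts[e$mate] <- rows[[length(rows)]]$pos[1]
    }
    # primary position of the mate
    for (r in seq_along(rows)) {
      m <- rows[[r]]$mate
      rows[[r]]$mate_pos <- mate_starts[if (m == 1L) 2L else 1L]
    }
    segs[[i]] <- do.call(rbind, rows)
  }
  segments <- do.call(rbind, segs)
  segments <- segments[order(segments$chrom, segments$pos, segments$read_id), , drop = FALSE]
  rownames(segments) <- NULL
  list(segments = segments, truth = truth)
}

# Reference mapping of an unedited read: one plain M segment.
plain_segment <- function(s, rl) {
  list(pos = s, cigar = paste0(rl, "M"), supp = FALSE)
}

# Reference mapping of a read from an allele with one edit. `s` is the
# 0-based read start on the allele; deletion [ds, de) on the reference is
# a junction point at allele coordinate ds; an insertion occupies allele
# coordinates [ds, ds + il).
edited_segments <- function(s, rl, ds, de, il, split_threshold) {
  e <- s + rl
  d <- de - ds
  if (d > 0) {
    if (e <= ds) return(plain_segment(s, rl))
    if (s >= ds) return(plain_segment(s + d, rl))
    a <- ds - s
    b <- e - ds
    if (d <= split_threshold) {
      return(list(pos = s, cigar = paste0(a, "M", d, "D", b, "M"), supp = FALSE))
    }
    # large deletion: split alignment, shorter flank supplementary
    list(
      pos = c(s, de),
      cigar = c(paste0(a, "M", b, "S"), paste0(a, "S", b, "M")),
      supp = c(a < b, a >= b)
    )
  } else if (il > 0) {
    if (e <= ds) return(plain_segment(s, rl))
    if (s >= ds + il) return(plain_segment(s - il, rl))
    if (s < ds && e > ds + il) {
      a <- ds - s
      b <- e - (ds + il)
      return(list(pos = s, cigar = paste0(a, "M", il, "I", b, "M"), supp = FALSE))
    }
    if (s < ds) {
      # read ends inside the insertion: clip the inserted tail
      a <- ds - s
      return(list(pos = s, cigar = paste0(a, "M", rl - a, "S"), supp = FALSE))
    }
    # read starts inside the insertion: clip the inserted head
    c0 <- ds + il - s
    list(pos = ds, cigar = paste0(c0, "S", rl - c0, "M"), supp = FALSE)
  } else {
    plain_segment(s, rl)
  }
}

#' Emit the surrogate genome and annotation tracks
#'
#' Returns the genome plus the repeat and polymorphic-indel interval
#' tracks consumed by the WGS filter cascade. Both tracks default to
#' empty; supplied intervals must not overlap the cut site unless
#' `allow_cut_overlap` is set (a track overlapping the on-target region
#' would silently veto the events under study).
#'
#' @param pop a [clone_population()]
#' @param repeats,polymorphic optional interval data.frames (`chrom`,
#'   `start`, `end`; 0-based half-open)
#' @param allow_cut_overlap allow track intervals over the cut site
#' @return list with `genome` (named character vector), `repeats`,
#'   `polymorphic`
#' @export
emit_tracks <- function(pop, repeats = NULL, polymorphic = NULL,
                        allow_cut_overlap = FALSE) {
  ref <- pop$reference
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(repeats)) repeats <- empty
  if (is.null(polymorphic)) polymorphic <- empty
  if (!allow_cut_overlap) {
    for (tr in list(repeats, polymorphic)) {
      if (nrow(tr) && any(tr$chrom == ref$chrom &
                          tr$start < ref$cut_pos + 20L &
                          tr$end > ref$cut_pos - 20L)) {
        stop("track interval overlaps the cut site; pass allow_cut_overlap = TRUE if intended")
      }
    }
  }
  list(
    genome = stats::setNames(ref$locus_seq, ref$chrom),
    repeats = repeats,
    polymorphic = polymorphic
  )
}
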