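# Independent oracles, deliberately written without reference to the
# package implementation: a plain affine-gap Needleman-Wunsch with
# traceback, a window-by-window Hamming scanner, and a per-event
# re-check of the WGS filter cascade by direct interval arithmetic.

# ---- global affine-gap alignment oracle ---------------------------------

nw_oracle_align <- function(frag, ref, match = 2, mismatch = -4,
                            gap_open = -6, gap_extend = -1) {
  a <- strsplit(frag, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in (mis)match
  X <- matrix(NEG, n + 1, m + 1)   # ends with gap in ref (insertion)
  Y <- matrix(NEG, n + 1, m + 1)   # ends with gap in fragment (deletion)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- gap_open + i * gap_extend
  for (j in seq_len(m)) Y[1, j + 1] <- gap_open + j * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend,
                             Y[i, j + 1] + gap_open + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend,
                             X[i + 1, j] + gap_open + gap_extend)
    }
  }
  # traceback
  i <- n; j <- m
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  pa <- character(0); pb <- character(0)
  while (i > 0 || j > 0) {
    if (state == 1) {
      s <- if (a[i] == b[j]) match else mismatch
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state_next <- which.max(prev)
      pa <- c(a[i], pa); pb <- c(b[j], pb)
      i <- i - 1; j <- j - 1
      state <- state_next
    } else if (state == 2) {
      cand <- c(M[i, j + 1] + gap_open + gap_extend,
                X[i, j + 1] + gap_extend,
                Y[i, j + 1] + gap_open + gap_extend)
      state_next <- which.max(cand)
      pa <- c(a[i], pa); pb <- c("-", pb)
      i <- i - 1
      state <- state_next
    } else {
      cand <- c(M[i + 1, j] + gap_open + gap_extend,
                Y[i + 1, j] + gap_extend,
                X[i + 1, j] + gap_open + gap_extend)
      state_next <- c(1L, 3L, 2L)[which.max(cand)]
      pa <- c("-", pa); pb <- c(b[j], pb)
      j <- j - 1
      state <- state_next
    }
    if (i == 0 && j > 0) state <- 3
    if (j == 0 && i > 0) state <- 2
  }
  list(pattern = paste(pa, collapse = ""), subject = paste(pb, collapse = ""),
       score = max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
}

# Extract indels (maximal gap runs, adjacent del/ins merged) from a gapped
# alignment and left-align them; all independent code.
oracle_indels <- function(pattern, subject, ref) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  rb <- strsplit(ref, "")[[1]]
  gap <- p == "-" | s == "-"
  out <- data.frame(ref_start = integer(0), ref_span = integer(0),
                    alt_seq = character(0), length = integer(0),
                    stringsAsFactors = FALSE)
  ref_pos <- 0L
  k <- 1L
  while (k <= length(p)) {
    if (!gap[k]) {
      ref_pos <- ref_pos + 1L
      k <- k + 1L
      next
    }
    start0 <- ref_pos
    span <- 0L
    alt <- character(0)
    while (k <= length(p) && gap[k]) {
      if (p[k] == "-") { span <- span + 1L; ref_pos <- ref_pos + 1L }
      else alt <- c(alt, p[k])
      k <- k + 1L
    }
    alt <- paste(alt, collapse = "")
    # left-align (own loop)
    if (span > 0 && alt == "") {
      while (start0 > 0 && rb[start0] == rb[start0 + span]) start0 <- start0 - 1L
    } else if (span == 0 && nchar(alt) > 0) {
      L <- nchar(alt)
      while (start0 > 0 && rb[start0] == substr(alt, L, L)) {
        alt <- paste0(rb[start0], substr(alt, 1, L - 1))
        start0 <- start0 - 1L
      }
    }
    out <- rbind(out, data.frame(ref_start = start0, ref_span = span,
                                 alt_seq = alt, length = span - nchar(alt),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$ref_start), , drop = FALSE]
}

# ---- exhaustive Hamming scan oracle -------------------------------------

oracle_hamming_scan <- function(protospacer, genome, max_mm) {
  rc <- function(x) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  scan_one <- function(chrom, seq, pat, strand) {
    L <- nchar(seq)
    w <- nchar(pat)
    if (L < w) return(NULL)
    gi <- utf8ToInt(seq)
    pi <- utf8ToInt(pat)
    n_win <- L - w + 1L
    mm <- integer(n_win)
    bad <- logical(n_win)
    for (j in seq_len(w)) {
      g <- gi[j:(j + n_win - 1L)]
      mm <- mm + (g != pi[j])
      bad <- bad | !(g %in% utf8ToInt("A") | g %in% utf8ToInt("C") |
                       g %in% utf8ToInt("G") | g %in% utf8ToInt("T"))
    }
    hit <- which(!bad & mm <= max_mm)
    if (!length(hit)) return(NULL)
    data.frame(chrom = chrom, pos = hit - 1L, strand = strand,
               mismatches = mm[hit], stringsAsFactors = FALSE)
  }
  out <- list()
  for (chrom in names(genome)) {
    out[[length(out) + 1L]] <- scan_one(chrom, genome[[chrom]], protospacer, "+")
    out[[length(out) + 1L]] <- scan_one(chrom, genome[[chrom]], rc(protospacer), "-")
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- brute-force filter cascade oracle ----------------------------------

oracle_filter_cascade <- function(events, control_events, polymorphic, repeats,
                                  coverage_fun, min_size = 4, max_size = 1e5,
                                  pad = 5, poly_id = 0.8, max_cov = 250) {
  keep <- logical(nrow(events))
  reason <- rep(NA_character_, nrow(events))
  for (i in seq_len(nrow(events))) {
    sz <- events$end[i] - events$start[i]
    if (sz < min_size || sz > max_size) { reason[i] <- "size"; next }
    bad <- FALSE
    for (bp in c(events$start[i], events$end[i])) {
      for (cb in c(control_events$start, control_events$end)) {
        if (abs(bp - cb) <= pad) bad <- TRUE
      }
    }
    if (bad) { reason[i] <- "control_breakpoint"; next }
    poly_hit <- FALSE
    for (j in seq_len(nrow(polymorphic))) {
      if (polymorphic$chrom[j] != events$chrom[i]) next
      ov <- min(events$end[i], polymorphic$end[j]) - max(events$start[i], polymorphic$start[j])
      if (ov <= 0) next
      if (ov / sz >= poly_id &&
          ov / (polymorphic$end[j] - polymorphic$start[j]) >= poly_id) poly_hit <- TRUE
    }
    if (poly_hit) { reason[i] <- "polymorphic"; next }
    rep_hit <- FALSE
    for (bp in c(events$start[i], events$end[i])) {
      for (j in seq_len(nrow(repeats))) {
        if (repeats$chrom[j] != events$chrom[i]) next
        if (bp + pad >= repeats$start[j] && bp - pad < repeats$end[j]) rep_hit <- TRUE
      }
    }
    if (rep_hit) { reason[i] <- "repeat"; next }
    if (coverage_fun(events$chrom[i], events$start[i]) > max_cov ||
        coverage_fun(events$chrom[i], events$end[i]) > max_cov) {
      reason[i] <- "coverage"; next
    }
    keep[i] <- TRUE
  }
  list(keep = keep, reason = reason)
}
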