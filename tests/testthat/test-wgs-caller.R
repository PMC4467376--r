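# CIGAR/split-read extraction, read-level filters, deduplication, the
# filter cascade, frameshift classification and locus allele fractions.

test_that("CIGAR deletions are extracted with correct arithmetic", {
  segs <- make_seg("r1/1", 1000, "50M10D51M")
  obs <- extract_candidate_indels(segs)$deletions
  expect_equal(nrow(obs), 1)
  expect_equal(obs$start, 1050)    # 1000 + 50, CIGAR arithmetic oracle
  expect_equal(obs$end, 1060)
  expect_equal(obs$flank_left, 50)
  expect_equal(obs$flank_right, 51)
  expect_equal(obs$total_m, 101)
  expect_equal(obs$source, "cigar")
})

test_that("reads with a single mapping stretch contribute nothing", {
  obs <- extract_candidate_indels(make_seg("r1/1", 500, "101M"))
  expect_equal(nrow(obs$deletions), 0)
  expect_equal(nrow(obs$insertions), 0)
})

test_that("split segments on one chromosome yield the gap deletion", {
  segs <- rbind(
    make_seg("r1/1", 1950, "50M51S"),            # ends at ref 2000
    make_seg("r1/1", 3200, "50S51M", supp = TRUE) # resumes at 3200
  )
  obs <- extract_candidate_indels(segs)$deletions
  expect_equal(nrow(obs), 1)
  expect_equal(obs$start, 2000)
  expect_equal(obs$end, 3200)
  expect_equal(obs$source, "split")
  # different chromosomes: no join
  segs2 <- rbind(make_seg("r2/1", 1950, "50M51S", chrom = "chr1"),
                 make_seg("r2/1", 3200, "50S51M", chrom = "chr2", supp = TRUE))
  expect_equal(nrow(extract_candidate_indels(segs2)$deletions), 0)
  # opposite strands: no join
  segs3 <- rbind(make_seg("r3/1", 1950, "50M51S", strand = "+"),
                 make_seg("r3/1", 3200, "50S51M", strand = "-", supp = TRUE))
  expect_equal(nrow(extract_candidate_indels(segs3)$deletions), 0)
  # inconsistent query order (clips on the wrong sides): no join
  segs4 <- rbind(make_seg("r4/1", 1950, "51S50M"),
                 make_seg("r4/1", 3200, "51M50S", supp = TRUE))
  expect_equal(nrow(extract_candidate_indels(segs4)$deletions), 0)
})

test_that("insertions go to the side channel, not the deletion cascade", {
  obs <- extract_candidate_indels(make_seg("r1/1", 100, "50M5I46M"))
  expect_equal(nrow(obs$deletions), 0)
  expect_equal(nrow(obs$insertions), 1)
  expect_equal(obs$insertions$start, 150)
  expect_equal(obs$insertions$ins_len, 5)
})

test_that("unknown CIGAR operations name the offending record", {
  expect_error(extract_candidate_indels(make_seg("odd/1", 10, "50M5B46M")),
               "odd/1")
})

test_that("read-level mapping-stretch filters hold at their boundaries", {
  cfg <- wgs_config()
  keep <- function(cigar) {
    obs <- extract_candidate_indels(make_seg("r/1", 0, cigar))$deletions
    nrow(filter_read_level(obs, cfg))
  }
  expect_equal(keep("50M10D51M"), 1)  # stretches 50/51, total 101
  expect_equal(keep("20M5D81M"), 0)   # 20 < 25
  expect_equal(keep("47M5D47M"), 0)   # total 94 < 95
  expect_equal(keep("25M5D70M"), 1)   # both boundaries inclusive: 25 and 95
})

test_that("duplicate reads by outer coordinates count once towards support", {
  # five reads supporting [1050,1060); r1 and r5 share outer coordinates
  segs <- rbind(
    make_seg("r1/1", 1000, "50M10D51M", mate_pos = 1400),
    make_seg("r2/1", 1010, "40M10D61M", mate_pos = 1410),
    make_seg("r3/1", 1020, "30M10D71M", mate_pos = 1420),
    make_seg("r4/1", 1025, "25M10D76M", mate_pos = 1430),
    make_seg("r5/1", 1000, "50M10D51M", mate_pos = 1400)
  )
  obs <- extract_candidate_indels(segs)$deletions
  ev <- deduplicate_and_combine(obs, sample = "t")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$support, 4)
  # a 1 bp difference in start makes a distinct event
  segs2 <- rbind(make_seg("a/1", 1000, "50M10D51M"),
                 make_seg("b/1", 1001, "50M10D51M"))
  ev2 <- deduplicate_and_combine(extract_candidate_indels(segs2)$deletions)
  expect_equal(nrow(ev2), 2)
  # empty input
  expect_equal(nrow(deduplicate_and_combine(obs[0, ])), 0)
})

test_that("the filter cascade enforces every boundary as specified", {
  cfg <- wgs_config()
  mk_ev <- function(start, end) {
    data.frame(sample = "t", chrom = "chr1", start = start, end = end,
               size = end - start, support = 5L, source = "cigar",
               stringsAsFactors = FALSE)
  }
  no_ctrl <- mk_ev(1, 2)[0, ]
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
  run <- function(ev, ctrl = no_ctrl, poly = empty, reps = empty, cov = NULL) {
    filter_deletions(ev, ctrl, poly, reps, cov, cfg)
  }
  # size bounds: 3 dropped, 4 and 100000 kept, 100001 dropped
  expect_equal(run(mk_ev(100, 103))$tally[["size"]], 1)
  expect_equal(nrow(run(mk_ev(100, 104))$retained), 1)
  expect_equal(nrow(run(mk_ev(100, 100100))$retained), 1)
  expect_equal(run(mk_ev(100, 100101))$tally[["size"]], 1)
  # control breakpoint padding: within 5 bp dropped, 6 bp kept
  ctrl <- mk_ev(204, 500)
  expect_equal(run(mk_ev(200, 300), ctrl)$tally[["control_breakpoint"]], 1)
  expect_equal(nrow(run(mk_ev(210, 300), ctrl)$retained), 1)
  # polymorphic reciprocal overlap >= 0.8
  poly_same <- data.frame(chrom = "chr1", start = 1000, end = 1100)
  expect_equal(run(mk_ev(1000, 1100), poly = poly_same)$tally[["polymorphic"]], 1)
  poly_half <- data.frame(chrom = "chr1", start = 1000, end = 1050)
  expect_equal(nrow(run(mk_ev(1000, 1100), poly = poly_half)$retained), 1)
  # repeats at a padded breakpoint
  reps <- data.frame(chrom = "chr1", start = 295, end = 320)
  expect_equal(run(mk_ev(200, 300), reps = reps)$tally[["repeat"]], 1)
  far <- data.frame(chrom = "chr1", start = 320, end = 340)
  expect_equal(nrow(run(mk_ev(200, 300), reps = far)$retained), 1)
  # control coverage: 250 kept, 251 dropped (strict >)
  cov250 <- IRanges::RleList(chr1 = S4Vectors::Rle(c(0L, 250L, 0L), c(200, 1, 799)))
  cov251 <- IRanges::RleList(chr1 = S4Vectors::Rle(c(0L, 251L, 0L), c(200, 1, 799)))
  expect_equal(nrow(run(mk_ev(200, 300), cov = cov250)$retained), 1)
  expect_equal(run(mk_ev(200, 300), cov = cov251)$tally[["coverage"]], 1)
  # tracks are required
  expect_error(run(mk_ev(200, 300), poly = NULL), "required")
  # conservation: retained + dropped == input
  mixed <- rbind(mk_ev(100, 102), mk_ev(200, 300), mk_ev(1000, 1100))
  res <- run(mixed, ctrl, poly = poly_same)
  expect_equal(nrow(res$retained) + sum(res$tally), nrow(mixed))
  expect_equal(nrow(res$retained) + nrow(res$dropped), nrow(mixed))
})

test_that("the cascade agrees with brute-force interval arithmetic", {
  set.seed(31)
  cfg <- wgs_config()
  n_ev <- 120
  events <- data.frame(
    sample = "t", chrom = "chr1",
    start = sample.int(45000, n_ev),
    size = sample(c(1:20, 50, 200, 1500, 120000), n_ev, replace = TRUE),
    support = 3L, source = "cigar", stringsAsFactors = FALSE
  )
  events$end <- events$start + events$size
  ctrl <- data.frame(sample = "c", chrom = "chr1",
                     start = sample.int(45000, 30), size = 10L,
                     support = 2L, source = "cigar", stringsAsFactors = FALSE)
  ctrl$end <- ctrl$start + sample(5:500, 30, replace = TRUE)
  poly <- data.frame(chrom = "chr1", start = sample.int(45000, 15))
  poly$end <- poly$start + sample(c(5:30, 1500), 15, replace = TRUE)
  reps <- data.frame(chrom = "chr1", start = sample.int(45000, 15))
  reps$end <- reps$start + sample(10:80, 15, replace = TRUE)
  # control coverage from ~400 synthetic reads, with a pileup hotspot
  ctrl_segs <- rbind(
    make_seg(paste0("c", 1:400, "/1"), sample.int(45000, 400, replace = TRUE), "101M"),
    make_seg(paste0("h", 1:300, "/1"), 20000 + sample.int(50, 300, replace = TRUE), "101M")
  )
  cov <- compute_coverage(ctrl_segs, c(chr1 = 150000L))
  got <- filter_deletions(events, ctrl, poly, reps, cov, cfg)
  ora <- oracle_filter_cascade(
    events, ctrl, poly, reps,
    coverage_fun = function(chrom, p) as.numeric(cov[[chrom]][p + 1]),
    min_size = cfg$min_size, max_size = cfg$max_size, pad = cfg$control_pad,
    poly_id = cfg$polymorphic_identity, max_cov = cfg$max_control_coverage
  )
  expect_equal(nrow(got$retained), sum(ora$keep))
  expect_equal(paste(got$retained$start, got$retained$end),
               paste(events$start[ora$keep], events$end[ora$keep]))
  expect_equal(got$dropped$reason, ora$reason[!ora$keep])
})

test_that("frameshift classification follows exonic size modulo three", {
  exon <- list(chrom = "chr1", start = 1000, end = 1300)
  ev <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  expect_equal(classify_frameshift(ev(1100, 1107), exon), "frameshift")      # 7 = 3N+1
  expect_equal(classify_frameshift(ev(1100, 1106), exon), "in_frame")        # 6 = 3N
  expect_equal(classify_frameshift(ev(500, 600), exon), "no_coding_overlap")
  # partial overlap counts only the exonic bases
  expect_equal(classify_frameshift(ev(995, 1003), exon), "in_frame")         # 3 exonic
  # invariance under a constant coordinate shift
  set.seed(32)
  for (k in 1:20) {
    s <- sample.int(5000, 1); e <- s + sample.int(500, 1)
    shift <- sample.int(10000, 1)
    exon2 <- list(chrom = "chr1", start = exon$start + shift, end = exon$end + shift)
    expect_equal(classify_frameshift(ev(s, e), exon),
                 classify_frameshift(ev(s + shift, e + shift), exon2))
  }
})

test_that("locus allele fractions count event-supporting and wild-type reads", {
  exon <- list(chrom = "chr1", start = 950, end = 1250)
  cut <- 1055L
  ev <- data.frame(sample = "t", chrom = "chr1", start = 1050, end = 1060,
                   size = 10L, support = 80L, source = "cigar",
                   stringsAsFactors = FALSE)
  segs <- rbind(
    make_seg(paste0("d", 1:80, "/1"), 1000, "50M10D51M"),
    make_seg(paste0("w", 1:20, "/1"), 1005, "101M")
  )
  af <- allele_fractions_at_locus(segs, ev, exon, cut)
  expect_equal(unname(af$fractions["frameshift"]), 0.8)  # 10 = 3N+1
  expect_equal(unname(af$fractions["wt"]), 0.2)
  expect_equal(af$n_assigned, 100)
  # all contiguous M: pure wild type
  af_wt <- allele_fractions_at_locus(make_seg(paste0("w", 1:10, "/1"), 1005, "101M"),
                                     ev[0, ], exon, cut)
  expect_equal(unname(af_wt$fractions["wt"]), 1.0)
  # no reads near the cut: not-applicable, not zero
  af_na <- allele_fractions_at_locus(make_seg("far/1", 5000, "101M"),
                                     ev, exon, cut)
  expect_true(all(is.na(af_na$fractions)))
})

test_that("a biallelic knockout population shows essentially no wild-type reads", {
  cfg <- sim_config(seed = 41, wgs_depth = 30)
  pop <- population_preset("biallelic-ko", cfg)
  sim <- simulate_wgs_alignments(pop, cfg, sample = "T1")
  ev <- data.frame(sample = "T1", chrom = pop$reference$chrom,
                   start = pop$clones$del_start, end = pop$clones$del_end,
                   size = pop$clones$del_end - pop$clones$del_start,
                   support = 1L, source = "cigar", stringsAsFactors = FALSE)
  exon <- list(chrom = pop$reference$chrom, start = 1400, end = 1700)
  af <- allele_fractions_at_locus(sim$segments, ev, exon, pop$reference$cut_pos)
  expect_lte(unname(af$fractions["wt"]), 0.01)
})

test_that("planted tumour deletions are recovered and a clean control yields none", {
  cfg <- sim_config(seed = 42, wgs_depth = 25)
  pop <- population_preset("biallelic-ko", cfg)
  tum <- simulate_wgs_alignments(pop, cfg, sample = "T1")
  ctl <- simulate_wgs_alignments(pop, cfg, sample = "C1", control = TRUE,
                                 seed = 4200)
  tracks <- emit_tracks(pop)
  sl <- vapply(tracks$genome, nchar, integer(1))
  res <- call_wgs_sample(tum$segments, list(ctl$segments), tracks$polymorphic,
                         tracks$repeats, sl, sample = "T1")
  got <- res$retained[order(res$retained$size), ]
  expect_equal(got$start, sort_by_size(tum$truth)$start)
  expect_equal(got$end, sort_by_size(tum$truth)$end)
  expect_setequal(got$size, c(10, 1435))
  # control sample through the same cascade: zero retained events
  cres <- call_wgs_sample(ctl$segments, list(ctl$segments[0, ]),
                          tracks$polymorphic, tracks$repeats, sl, sample = "C1")
  expect_equal(nrow(cres$retained), 0)
})
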