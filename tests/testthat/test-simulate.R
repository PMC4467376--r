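# The synthetic-data generator: clone populations, amplicon reads, WGS
# alignments, tracks; determinism and truth conservation.

test_that("simulated populations carry the requested clone spectrum", {
  cfg <- sim_config(seed = 61)
  set.seed(61)
  ref <- build_reference()
  pop <- simulate_clones(ref, cfg, major_freqs = c(0.5, 0.25, 0.15),
                         tail_mass = 0.10)
  expect_equal(nrow(pop$clones), 3 + cfg$n_background_clones)
  expect_equal(sum(pop$clones$freq), 1.0, tolerance = 1e-12)
  expect_equal(pop$wt_freq, 0, tolerance = 1e-12)
  expect_equal(sum(sort(pop$clones$freq, decreasing = TRUE)[1:3]), 0.90,
               tolerance = 1e-12)
  # every edit overlaps the cut region; insertions < 10 bp
  expect_true(all(pop$clones$del_start <= ref$cut_pos + 20))
  expect_true(all(pop$clones$del_end >= ref$cut_pos - 20))
  expect_true(all(nchar(pop$clones$insert_seq) < 10))
  # no clones: pure wild type
  ctrl <- population_preset("control", cfg)
  expect_equal(nrow(ctrl$clones), 0)
  expect_equal(ctrl$wt_freq, 1)
  # biallelic knockout: zero wild-type mass
  ko <- population_preset("biallelic-ko", cfg)
  expect_equal(ko$wt_freq, 0)
  # over-committed frequencies are an error
  expect_error(simulate_clones(ref, cfg, major_freqs = c(0.7, 0.4),
                               tail_mass = 0.1), "more than 1")
})

test_that("same seed gives byte-identical FASTQ and SAM outputs", {
  cfg <- sim_config(seed = 62, n_pairs_per_amplicon = 300, wgs_depth = 5)
  run_once <- function() {
    pop <- population_preset("polyclonal-mb", cfg)
    sim <- simulate_amplicon_reads(pop, cfg)
    wgs <- simulate_wgs_alignments(pop, cfg)
    d <- tempfile(); dir.create(d)
    write_fastq_pairs(sim$pairs, file.path(d, "r1.fastq"), file.path(d, "r2.fastq"))
    write_sam(wgs$segments, vapply(emit_tracks(pop)$genome, nchar, integer(1)),
              file.path(d, "t.sam"))
    unname(vapply(file.path(d, c("r1.fastq", "r2.fastq", "t.sam")),
                  function(f) unname(tools::md5sum(f)), character(1)))
  }
  expect_identical(run_once(), run_once())
})

test_that("amplicon truth records renormalised fractions and dropouts", {
  cfg <- sim_config(seed = 63, n_pairs_per_amplicon = 5000)
  set.seed(63)
  ref <- build_reference()
  # one clone whose deletion removes amplicon 1's forward primer
  a1 <- ref$panel[1, ]
  clones <- data.frame(
    del_start = c(a1$ref_offset + 2L, ref$cut_pos - 5L),
    del_end = c(ref$cut_pos + 2L, ref$cut_pos + 5L),
    insert_seq = c("", ""),
    freq = c(0.4, 0.4),
    stringsAsFactors = FALSE
  )
  pop <- clone_population(ref, clones)
  sim <- simulate_amplicon_reads(pop, cfg)
  t1 <- sim$truth[sim$truth$amplicon == a1$name, ]
  expect_true(t1$dropout[1])
  expect_equal(t1$expected_fraction[1], 0)
  # surviving clone's mass renormalises: 0.4 / (1 - 0.4)
  expect_equal(t1$expected_fraction[2], 0.4 / 0.6, tolerance = 1e-12)
  # no reads of the dropped clone in amplicon 1, and observed fraction of
  # the surviving clone is near its renormalised truth
  dm <- demultiplex_reads(sim$pairs, ref$panel)
  sub <- dm$assigned[[a1$name]]
  m <- merge_pairs(sub$seq1, sub$seq2, sub$qual1, sub$qual2, caller_config())
  # fragment of the surviving 10 bp deletion clone; fragment length is
  # invariant to substitution errors, so count by length
  frag2 <- edit_seq(a1$ref_seq, clones$del_start[2] - a1$ref_offset,
                    clones$del_end[2] - a1$ref_offset)
  expect_gt(mean(nchar(m) == nchar(frag2), na.rm = TRUE), 0.4 / 0.6 - 0.03)
  # the dropped clone leaves no fragments of its (much shorter) length
  drop_len <- nchar(a1$ref_seq) - (clones$del_end[1] - clones$del_start[1])
  expect_equal(sum(nchar(m) == drop_len, na.rm = TRUE), 0)
})

test_that("error-free wild-type reads reproduce the reference fragments", {
  cfg <- sim_config(seed = 64, n_pairs_per_amplicon = 200, error_rate = 0)
  pop <- population_preset("control", cfg)
  sim <- simulate_amplicon_reads(pop, cfg)
  res <- call_amplicon_sample(sim$pairs, pop$reference$panel,
                              caller_config(min_fragment_count = 1))
  expect_equal(nrow(res$calls), 0)
  expect_setequal(res$fragments$seq, pop$reference$panel$ref_seq)
})

test_that("WGS simulation respects depth, control and truth contracts", {
  cfg0 <- sim_config(seed = 65, wgs_depth = 0)
  pop <- population_preset("biallelic-ko", cfg0)
  none <- simulate_wgs_alignments(pop, cfg0)
  expect_equal(nrow(none$segments), 0)
  # an empty SAM still carries a valid header
  sl <- vapply(emit_tracks(pop)$genome, nchar, integer(1))
  f <- tempfile(fileext = ".sam")
  write_sam(none$segments, sl, f)
  expect_equal(nrow(read_alignment_segments(f)), 0)
  # control: no somatic truth
  cfg <- sim_config(seed = 65, wgs_depth = 20)
  ctl <- simulate_wgs_alignments(pop, cfg, control = TRUE)
  expect_equal(nrow(ctl$truth), 0)
  # tumour truth lists each somatic deletion once
  tum <- simulate_wgs_alignments(pop, cfg)
  expect_equal(sort(tum$truth$size), c(10, 1435))
  # large deletions appear as split segments, small as CIGAR D
  obs <- extract_candidate_indels(tum$segments)$deletions
  expect_true(all(obs$source[obs$end - obs$start > 1000] == "split"))
  expect_true(all(obs$source[obs$end - obs$start == 10] == "cigar"))
})

test_that("tracks default to empty and refuse cut-site overlaps unless asked", {
  cfg <- sim_config(seed = 66)
  pop <- population_preset("biallelic-ko", cfg)
  tr <- emit_tracks(pop)
  expect_equal(names(tr$genome), pop$reference$chrom)
  expect_equal(nrow(tr$repeats), 0)
  expect_equal(nrow(tr$polymorphic), 0)
  bad <- data.frame(chrom = pop$reference$chrom,
                    start = pop$reference$cut_pos - 2L,
                    end = pop$reference$cut_pos + 2L)
  expect_error(emit_tracks(pop, repeats = bad), "cut site")
  ok <- emit_tracks(pop, repeats = bad, allow_cut_overlap = TRUE)
  expect_equal(nrow(ok$repeats), 1)
})

test_that("a planted repeat at a breakpoint removes that event downstream", {
  cfg <- sim_config(seed = 67, wgs_depth = 25)
  pop <- population_preset("biallelic-ko", cfg)
  small_del <- pop$clones[pop$clones$del_end - pop$clones$del_start == 10, ]
  rep_track <- data.frame(chrom = pop$reference$chrom,
                          start = small_del$del_start - 2L,
                          end = small_del$del_start + 2L)
  tum <- simulate_wgs_alignments(pop, cfg, sample = "T1")
  ctl <- simulate_wgs_alignments(pop, cfg, sample = "C1", control = TRUE,
                                 seed = 670)
  tr <- emit_tracks(pop, repeats = rep_track, allow_cut_overlap = TRUE)
  sl <- vapply(tr$genome, nchar, integer(1))
  res <- call_wgs_sample(tum$segments, list(ctl$segments), tr$polymorphic,
                         tr$repeats, sl, sample = "T1")
  expect_false(any(res$retained$size == 10))
  expect_true(any(res$dropped$reason == "repeat"))
  expect_true(any(res$retained$size == 1435))
})

test_that("a planted polymorphic deletion identical to a somatic one is filtered", {
  cfg <- sim_config(seed = 68, wgs_depth = 25)
  pop <- population_preset("biallelic-ko", cfg)
  big <- pop$clones[pop$clones$del_end - pop$clones$del_start == 1435, ]
  poly <- data.frame(chrom = pop$reference$chrom,
                     start = big$del_start, end = big$del_end)
  tum <- simulate_wgs_alignments(pop, cfg, sample = "T1")
  ctl <- simulate_wgs_alignments(pop, cfg, sample = "C1", control = TRUE,
                                 seed = 680)
  tr <- emit_tracks(pop, polymorphic = poly, allow_cut_overlap = TRUE)
  sl <- vapply(tr$genome, nchar, integer(1))
  res <- call_wgs_sample(tum$segments, list(ctl$segments), tr$polymorphic,
                         tr$repeats, sl, sample = "T1")
  expect_false(any(res$retained$size == 1435))
  expect_true(any(res$dropped$reason == "polymorphic"))
})

test_that("observed clone fractions sit inside their binomial interval", {
  cfg <- sim_config(seed = 69, n_pairs_per_amplicon = 10000)
  set.seed(69)
  ref <- build_reference()
  clones <- data.frame(del_start = ref$cut_pos - 5L, del_end = ref$cut_pos + 5L,
                       insert_seq = "", freq = 0.3, stringsAsFactors = FALSE)
  pop <- clone_population(ref, clones)
  sim <- simulate_amplicon_reads(pop, cfg)
  # count pairs of the edited allele in amplicon 3 by exact fragment match
  a <- ref$panel[3, ]
  dm <- demultiplex_reads(sim$pairs, ref$panel)
  sub <- dm$assigned[[a$name]]
  m <- merge_pairs(sub$seq1, sub$seq2, sub$qual1, sub$qual2, caller_config())
  frag <- edit_seq(a$ref_seq, clones$del_start - a$ref_offset,
                   clones$del_end - a$ref_offset)
  # fragment length is invariant to substitution errors, so the fraction
  # of merged fragments at the edited length estimates the clone frequency
  obs <- mean(nchar(m) == nchar(frag), na.rm = TRUE)
  ci99 <- 2.58 * sqrt(0.3 * 0.7 / sum(!is.na(m)))
  expect_lt(abs(obs - 0.3), ci99 + 0.005)
})
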