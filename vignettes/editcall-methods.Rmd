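---
title: "Methods: calling CRISPR/Cas9 editing outcomes in polyclonal tumours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling CRISPR/Cas9 editing outcomes in polyclonal tumours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`editcall` characterises the repair outcomes of a somatic CRISPR/Cas9 cut in
a polyclonal cell population — typically a tumour induced by disrupting a
tumour suppressor in vivo. Each transfected cell repairs the double-strand
break independently by non-homologous end joining, so a tumour is a mixture
of clones, each carrying its own indel allele at the target locus: a few
predominant clones and a long tail of rare ones, with deletions ranging from
1 bp to several kb and insertions usually under 10 bp. The package covers
four measurement channels and one generator:

1. **Amplicon deep sequencing** of the target locus with several staggered
   primer pairs, for sensitive quantification of small indels and of
   clonality.
2. **Whole-genome sequencing (WGS)** of tumour and matched control, for
   deletions of any size (large deletions remove primer sites and are
   invisible to amplicons) and for genome-wide off-target screens.
3. **Guide off-target scanning** by Hamming-distance matching of the
   protospacer, plus two recurrence screens over WGS deletion calls.
4. **SURVEYOR assays**, converting cleavage band intensities to a
   percent-modified estimate by a closed form.
5. A **synthetic-data generator** producing all of the above from a known
   clone population, so every stage is testable against ground truth.

# Amplicon indel calling

The chain is: demultiplex → merge → collapse → predominant-per-length →
annotate → threshold → clonality.

* **Demultiplexing** assigns a read pair to an amplicon only when read 1
  begins with the forward primer and read 2 with the reverse primer,
  character for character, with no mismatches; both read orientations are
  accepted because the sequencing orientation of a pair is arbitrary. Pairs
  carrying an error inside a primer are deliberately discarded — with a
  0.1% per-base error and ~20 bp primers this loses about 4% of pairs,
  uniformly across alleles, so fractions are unaffected.
* **Merging** reverse-complements the mate and slides it against the
  forward read. The accepted overlap maximises matching bases subject to an
  overlap of at least 10 bp and at most 10% mismatches inside the overlap;
  ties go to the longer overlap, and at disagreeing positions the
  higher-quality base wins (ties to the forward read). This replaces an
  external statistical merger with a self-contained, testable rule; the
  merged length is always `len(fwd) + len(rev) − overlap`.
* **Collapsing** combines identical merged fragments per amplicon and
  removes fragments occurring fewer than 100 times (a fragment at exactly
  100 is kept). At the depths this assay is run (tens of thousands of pairs
  per amplicon and up), real clones produce thousands of identical
  fragments while error variants stay in the tens, so the filter separates
  signal from noise without modelling qualities.
* **Predominant per length**: when several retained fragments of one
  amplicon share a length, only the most frequent sequence is kept (ties:
  lexicographically smallest, for determinism); the rest are reported
  separately. Substitution errors conserve length, so the predominant
  sequence is the best representative of its length class.
* **Annotation** aligns each non-reference fragment end-to-end against the
  amplicon reference (match +2, mismatch −4, gap open −6, gap extend −1 —
  scores that favour one consolidated gap over scattered gaps, matching the
  single-deletion repair outcomes that dominate Cas9 cuts). Every maximal
  gap run becomes one indel; pure insertions and deletions are left-aligned
  so that the staggered amplicons, which share locus coordinates, report
  byte-identical representations. Indel length is signed: affected
  reference length minus alternative length, positive for deletions.
* **Calling** merges indels across amplicons by their canonical
  `(start, span, alt)` identity and requires at least 0.5% of reads in each
  of at least two amplicons (both bounds inclusive; both per-amplicon and
  pooled-fraction interpretations are implemented, per-amplicon being the
  default). Requiring two independent PCR products suppresses
  amplicon-specific artefacts.
* **Read-fraction denominator.** Fractions divide by the per-amplicon
  merged read count *after* the rare-fragment filter (a flag restores the
  pre-filter denominator). This is a deliberate design choice: a read with
  at least one substitution error drops out of its clone's collapsed
  fragment, at a rate `1 − (1−e)^L` that is essentially the same for every
  allele (≈ 34% at e = 0.001, L ≈ 420 bp). Dividing by the post-filter
  total cancels this loss and recovers unbiased allele fractions; dividing
  by all merged reads would deflate every fraction by that factor and no
  threshold-based pipeline could recover frequencies to ±0.02 under
  realistic error rates.
* **Clonality** counts called indels longer than 1 bp (strict) and reports
  the read share of the top k indels (k = 1..5) among all called indels,
  using each indel's mean across-amplicon fraction.

# WGS deletion calling

Both mate ends are treated as independent observations. Two evidence
channels feed the caller: CIGAR deletions (a D run between M runs inside
one alignment) and split reads (two alignment segments of one read end on
the same chromosome and strand, in consistent reference/query order; the
reference gap between them is the deletion). Insertion observations are
extracted too but routed to a side channel — the filter cascade is
deletion-centric.

Read-level filters require every mapping stretch of the read to be at
least 25 bp and at least 95 bp mapped in total; a 101 bp read must
therefore anchor solidly on both sides of the junction. Observations of
the same deletion are combined, counting reads once when they share outer
alignment coordinates on both ends (the standard coordinate-based
definition of a putative PCR duplicate).

The filter cascade then applies, in fixed order so the drop tally is
reproducible: size within [4 bp, 100 kb]; no breakpoint within 5 bp of any
breakpoint in the pooled control samples; no reciprocal overlap ≥ 0.80
with a known polymorphic indel interval (a breakpoint-distance mode is
available; interval overlap stands in for sequence identity because
annotation tracks are interval-typed); no breakpoint (±5 bp) in an
annotated simple repeat; and no breakpoint at a position with combined
control coverage above 250 (250 kept, 251 dropped). Events are attributed
to the first failing filter.

**Frameshift classification** uses only the deletion's intersection with
the coding exon: no overlap → no coding consequence; an exonic loss of 3N
bases → in frame; otherwise frameshift.

**Allele fractions at the locus** classify every read end overlapping the
cut position (±30 bp by default) as supporting one of the identified locus
deletions (its own deletion observation matches the event exactly), as
wild type (one contiguous mapping stretch across the cut), or as
unassigned. This read-assignment replaces re-alignment of all reads to an
indel-resolved reference set: with alignments already in hand, exact
breakpoint matching yields the same per-read labels at desk scale, without
an external aligner.

# Off-target screens

`scan_genome` reports every 20-mer window on either strand within a
Hamming mismatch budget (no bulges), with windows containing N never
matching. The PAM is not required by default — mismatch-mapping of the
bare 20-mer is how non-targeting control guides are validated with
mismatch-mapping tools — and can be enforced
as NGG with a flag. Deletion calls are matched to guide sites when a site
lies within 30 bp of a breakpoint (guide length plus 10: the cut sits 3 bp
inside the protospacer and end resection widens breakpoints; no tighter
figure is defensible from first principles, so the window is a flag).
Two screens then look for clonally enriched off-target loci among
clustered deletion calls (padded-interval transitive clustering, pad 5 bp,
matching the control-breakpoint padding): loci recurrently mutated in
every tumour sample, and loci where one sample carries two or more
distinct deletions. In a cohort edited only at the intended site, both
screens return exactly the on-target cluster and nothing else — the
"no detectable off-targets" result shape.

# SURVEYOR quantification

The cleaved fraction is `sum(cleaved)/(sum(cleaved)+parent)` after
per-band background subtraction floored at zero (the standard convention;
no molar length correction is applied). Re-annealing a pool with modified
fraction p produces heteroduplex — hence cleavable — molecules with
probability `1−(1−p)²` under random pairing, so
`% modified = (1 − sqrt(1 − fraction cleaved)) × 100`. The transform is
strictly increasing with exact endpoints 0 → 0 and 1 → 100 and inverts as
`fc = 1 − (1 − p/100)²`.

# The synthetic-data generator

The generator emulates the study's sequencing design: a ~3 kb surrogate
locus of seeded random DNA with the Ptch1.1 protospacer planted at
the cut position (PAM TGG) and the five staggered Ptch1 primer pairs
planted so that every ~420 bp amplicon spans the cut; 251 bp paired-end
amplicon reads; 101 bp paired-end WGS records at 23.3× mean coverage by
default; constant Q37 qualities; uniform substitution errors at 0.1%.
Reads are emitted pre-aligned (SAM with correct CIGARs; deletions above
50 bp become split segments, as an aligner would represent them) because
the pipeline consumes alignments — alignment itself is out of scope.

Clone presets: `polyclonal-mb` gives three predominant clones 95% of the
mass at relative weights 0.5/0.3/0.2 with a 20-clone tail sharing 5% and
no wild type (the biallelically disrupted, polyclonal tumour picture;
the real clone-frequency distribution beyond "few predominant clones" is
unknown, so the spectrum is configuration, not assertion);
`biallelic-ko` gives two clones at 0.5 — a 10 bp frameshift deletion and a
1,435 bp deletion, the canonical large-deletion fixture; `control` is pure
wild type. Alleles whose edit removes a primer site yield no reads for
that amplicon; the remaining frequencies renormalise (PCR amplifies what
can still prime) and the truth table records the dropout.

What the generator does *not* model — and what passing tests therefore do
not establish about real data: microhomology-driven indel spectra, PCR
amplification bias between alleles, instrument-specific quality profiles,
chimeric reads, and mapping ambiguity in repetitive genomes. The surrogate
locus is unique by construction, so mapping is exact; on real genomes the
repeat and coverage filters carry the weight that uniqueness carries here.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; 1-based only in
  VCF and SAM output (VCF indels use the left-aligned anchor-base form).
* All count thresholds are inclusive exactly as documented: `<100`
  removes, 100 stays; `≥0.5%`, `≥2` amplicons, `≥25 bp` stretches,
  `≥95 bp` mapped, sizes in `[4, 100000]`; coverage `>250` removes.
* Ties: predominant-fragment selection breaks count ties by
  lexicographically smallest sequence; merge-overlap ties go to the longer
  overlap.
* Zero-read amplicons are excluded from denominators with a warning; an
  empty call list yields `n = 0` and not-applicable (NA) shares, never
  0/0; zero assigned locus reads yield NA fractions, not zeros.
* Annotation tracks are required arguments (possibly empty tables) so a
  forgotten track cannot silently disable a filter.
* Determinism: a fixed seed makes generator outputs byte-identical; all
  sort orders and tie-breaks are total.

# Problem sizes used by the test-suite and acceptance script

Parameter recovery runs the generator at its study-scale defaults: 50,000
pairs per amplicon across five amplicons (250,000 pairs per sample) with
the 0.1% error rate, recovering the three predominant clones to within
±0.02; WGS recovery runs at 25× on the 3 kb locus; the off-target cohort
uses three tumours and two pooled controls at 35×, where the rarest
predominant clone still leaves a handful of junction-spanning reads per
sample. Oracle-equivalence checks use fragments up to 60 nt against a
brute-force dynamic-programming aligner, 10 kb genomes against an
exhaustive Hamming scan, and ~100-event fixtures against a brute-force
filter cascade.

# Known limitations

* Guide matching is ungapped; bulged off-target sites are out of scope, as
  are cutting-efficiency scores.
* The polymorphic-indel filter compares intervals, not sequences; a
  catalogue with allele sequences would allow true identity matching.
* The amplicon caller does not call substitutions, handle UMIs, or trim
  adapters; input reads are assumed primer-anchored, as the demultiplexing
  rule requires.
* Allele fractions at the locus assign reads by exact breakpoint match;
  reads from alleles whose representation differs from the called event
  (e.g. an untrimmed microhomology) land in the unassigned class rather
  than being force-assigned.
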