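---
title: "Methods: genic-SSR mining and trio SNP zygosity analysis"
author: "triohet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genic-SSR mining and trio SNP zygosity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triohet)
```

# The study design

`triohet` implements the computational core of a transcriptome marker
study on a parent/parent/F1-hybrid trio: two named parental varieties
and their cross, each leaf-RNA-sequenced, with a non-redundant
assembled unigene set serving both as the SSR mining substrate and as
the alignment reference for SNP discovery. The package deliberately
starts *after* assembly and alignment (a unigene FASTA and a SAM file
are inputs) and stops *before* functional annotation and wet-lab
validation.

# Microsatellite mining

## Detection model

An SSR locus is a maximal perfect tandem repeat of a primitive motif
of 2–6 bases. Three rules fix what "one locus" means:

* **Whole units only.** A tract's span covers complete motif units; a
  trailing partial unit extends neither the span nor the repeat
  count. `repeat_count = floor(run_length / unit_size)` where the run
  is extended by perfect matching.
* **Primitivity.** A stretch of `(ATC)₉` is never additionally
  reported as `(ATCATC)₄`: a motif that is itself a repetition of a
  shorter unit is suppressed, because the shorter unit's scan already
  covers the tract.
* **One report per tract.** When maximal runs of distinct motifs
  overlap (possible at repeat junctions), the longer run wins; ties
  go to the leftmost, then to the smaller unit. Among equal-length
  phase shifts of the same tract the leftmost start wins naturally,
  because the scanner anchors runs at their leftmost matching
  position.

Runs containing `N` are broken at the `N`; mononucleotide runs are
never scanned by default (`unitSizes = 2:6`), though the criteria
object accepts 1 for generality.

The reiteration thresholds default to ≥6 for di-nucleotide and ≥5
for tri- to hexa-nucleotide motifs — the usual transcriptome-SSR
(MISA) configuration. With these thresholds the shortest reportable
tract is 12 bp, so the separate `minTotalLen = 10` filter is
redundant at the defaults; it is implemented anyway because both
knobs are independently configurable.

## Motif canonicalization

Frequency tables pool motifs that describe the same tract on either
strand or in a different phase: `canonicalMotif()` returns the
lexicographically smallest string among all cyclic rotations of the
motif and of its reverse complement. Brute-force enumeration confirms
the expected partition sizes: 4 classes for dinucleotides (AC, AG,
AT, CG) and 10 for trinucleotides.

## Compound SSRs and Type I/II

Two loci closer than `compoundMaxGap` (default 100 bp, the common
interruption window for "compound" microsatellites) are flagged
compound, transitively along chains, and excluded from marker design
— compound SSRs amplify poorly and show the least polymorphism.
Retained loci with tracts ≥20 bp are Type I, the class worth
synthesizing primers for; shorter ones are Type II.

# Primer design

Candidate primers are enumerated exhaustively on both flanks: forward
primers end strictly before the SSR tract, reverse primers start
strictly after it, so the product always contains the tract. Hard
constraints (all must hold): primer length 20–25 bases, product
100–250 bp, GC 40–60 %, and at most a single consecutive G or C at
the 3′ terminus of either primer. Among feasible pairs the returned
one minimizes

```
score = |Tm_f − 65| + |Tm_r − 65| + |Tm_f − Tm_r|
        + (|GC_f − 50| + |GC_r − 50|) / 10
```

with deterministic tie-breaks (smaller forward start, then smaller
product). The melting temperature uses the long-oligo approximation
`Tm = 81.5 + 0.41·GC% − 675/N`, standard for 20–25-mers and the
reason a 14-base minimum is enforced; the weights put Tm proximity
and inter-primer Tm balance first with GC deviation as a tie-breaker
at one-tenth weight. This scoring is the package's own choice — any
monotone preference over the same hard constraints would be
defensible — and is therefore deterministic and documented rather
than tuned.

The 3′-clamp wording "only single consecutive G or C" is read as: the
maximal run of identical G's or identical C's ending at the terminal
base has length ≤1 (so `…GC` passes, `…GG` fails). A stricter
reading (at most one G-or-C among the last *k* bases) exists; the
run-based reading is the conventional one for clamp filters and is
the one implemented.

Marker ids `MSSR1, MSSR2, …` are assigned in transcript order, then
locus order, over loci for which a pair exists; loci whose flanks are
too short or fail the constraints are counted, not numbered.

# SNP calling

## Variety tagging and pileup

Reads carry their variety as a header suffix `read_id|VARIETY` (the
pipe is rare in read names and survives SAM round trips), so a pooled
alignment remains attributable per variety. `buildPileup()` walks
each CIGAR: `M/=/X` contribute (base, quality) to reference columns,
`I/S` consume read only, `D` consumes reference only; `N` base calls
are ignored. Indels never generate candidate alleles — this is a
substitution-SNP caller only.

## The three filters

A site is reported when

1. pooled depth across the three varieties is ≥ `minTotalDepth` (10);
2. the mean Phred quality over **all** bases piled at the position is
   ≥ `minAvgBaseQual` (25) — averaging over all bases, not
   alt-allele bases only, matches a plain depth-weighted base-quality
   filter and keeps the statistic monotone;
3. an allele counts as *supported* only with ≥ `minAlleleReads` (2)
   reads within at least one variety; sub-threshold alleles are
   noise and do not count toward the allele number.

Sites with more than two supported alleles are dropped as
multi-allelic. One or two supported alleles with at least one
differing from the reference are reported: a single supported
non-reference allele is a homozygous-variant site (reference side
reported with its actual, sub-threshold depth); two supported
non-reference alleles are ordered lexicographically with the original
reference base kept in a separate column. Pooling filter 1 across
varieties (rather than per variety) reflects that the source design
aligned all tagged reads together; it is configurable.

Emitted-site count is provably monotone (non-increasing) in
`minTotalDepth` and `minAvgBaseQual`. In `minAlleleReads` it is
monotone only while at most two distinct alleles are piled per
position: with sequencing errors, raising the threshold can
de-support an error allele and *rescue* a formerly multi-allelic
site. The property tests therefore exercise the first two thresholds
on error-bearing simulations and the third on error-free ones.

## Zygosity and the eight trio classes

Per variety and site: HT if both alleles reach support, HM if exactly
one does, NOCALL otherwise. The ordered (parent, parent, hybrid)
triple maps bijectively onto classes 1–8; triples containing a NOCALL
are excluded from the trio table (the table covers sites with calls
common to all three genotypes) and counted. Class 5
(HT, HT → hybrid HM) is typically a shallow-coverage artifact in real
data; the classifier reports what the depths support and leaves the
interpretation to the analyst.

Derived metrics: per-variety HT counts and percentages, novel
heterozygosity (class 1), maintained (classes 2–4), lost (classes
5, 7, 8), and the SNPs-per-transcript distribution over transcripts
with ≥1 classified site. Reports print percentages at 2 decimal
places.

# The simulator

`simulateTrioExperiment()` emulates the statistical structure the
analysis assumes:

* **Reference**: uniform random transcripts, lengths 400–1500 bp by
  default; with probability `ssrProb` a transcript carries one
  embedded perfect SSR (unit 2–6, reiterations sampled from the
  threshold up to threshold+7 so tracts straddle the 20 bp Type I
  boundary) with ≥60 bp flanks — enough for primer windows.
* **Genotypes**: biallelic sites placed ≥ one read length from the
  transcript ends and from each other, so each read overlaps at most
  one site and the pileup/caller interaction stays analyzable (a
  deliberate simplification, configurable by construction). Direct
  mode draws a class from `classProportions` and then genotypes
  uniformly among configurations consistent with the class pattern;
  both-parents-HM with a hybrid HT forces contrasting parental
  homozygotes, and the all-HM class draws among homozygous patterns
  where at least one variety differs from the reference, keeping the
  site detectable. Mendelian mode draws parental alleles
  independently (Bernoulli ½ per haplotype) and the hybrid inherits
  one allele from each parent. Direct mode is *not* constrained to
  Mendelian consistency — it exists to hit target class proportions
  exactly, including the artifact classes real data contain.
* **Reads**: per variety, reads split evenly over the two haplotypes
  at uniform starts to reach the target coverage (expected count
  `coverage · length / readLen` per transcript and variety, within
  one read). Substitution errors at `errorRate` to a uniformly
  chosen different base; constant Phred quality. All randomness
  flows from one seed; identical configs give identical outputs.

Defaults mirror the emulated study: 50 bp reads (short-read
platform), base quality 30, 1 % substitution error, 30× per-variety
coverage, and class proportions equal to the published eight-class
distribution of the mango trio (22,306 sites).

## What the simulator does not emulate

No expression-level variation (uniform coverage), no indels or splice
structure, no platform-specific or position-dependent error profiles,
and — most consequentially — **constant base quality**. With constant
quality the average-quality filter cannot discriminate errors from
real alleles, so at a 1 % error rate the caller reports
error-supported false sites that a real quality model would suppress
(in the emulated study roughly half of the raw sites fell to the
quality filters). Recovery statements on error-bearing simulations
are therefore made *at truth sites*; the error-free setting supports
the stronger claim of exact recovery with zero false sites. Passing
tests show the pipeline arithmetic is right, not that real RNA-seq
data would yield these error rates.

# Numerical and scale choices

Test and acceptance problem sizes were chosen as the smallest that
make the statistical claims meaningful: the scanner/oracle
equivalence uses 1,000 random 1 kb sequences; parameter recovery uses
10,000 sites on 500 transcripts of ~1.2 kb at 30× — there the
per-class binomial standard error is ~0.2–0.5 percentage points, and
recovery is required within 3 SE (error-free) or 4 SE (1 % error,
which adds a small systematic HM→HT misclassification of ~0.5 % per
homozygous variety-site). Percent summaries are reported at 2
decimals; comparisons against published values round to the precision
those values were printed at (one or two decimals).

Degenerate inputs are defined, not special-cased: empty locus sets
give all-zero summaries, an empty classified table gives 0 %
heterozygosity, zero coverage gives empty read sets, and header-only
tables round-trip through the TSV layer.

# Known limitations

* The SSR scanner targets transcript-scale inputs; no suffix-array
  optimizations for genome-scale scanning.
* Imperfect (interrupted) microsatellites are out of scope; compound
  loci are flagged and excluded, not merged into compound motifs.
* Primer design checks the stated hard constraints only — no
  nearest-neighbor thermodynamics, hairpin/dimer screening or
  multiplex compatibility.
* The caller uses hard thresholds, not genotype likelihoods; with
  shallow hybrid coverage, class-5 artifacts are reported as
  observed.
* BAM/CRAM and gzip inputs are not parsed; SAM text, FASTA and
  Phred+33 FASTQ only.
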