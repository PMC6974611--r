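---
title: "Methods: consensus truth sets and concordance scoring for NGS proficiency testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus truth sets and concordance scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngseqa)
```

## The model

A proficiency-testing round collects, from each participating laboratory,
a VCF of called variants and a BED declaring the region of interest (ROI)
the lab actually analysed. Because no perfect external truth exists for an
arbitrary clinical panel, the truth is *voted*: a normalized call
`(chrom, pos, ref, alt[, genotype class])` enters the participant consensus
iff

1. the site lies in the declared ROI of at least `min_participants` labs
   (default 7), and
2. the labs making that exact call are at least `agreement_fraction`
   (default 0.75) of the covering labs.

Two readings of "these participants agreed" are possible; this package
takes the denominator to be the *covering* labs, so a covering lab that
calls nothing at the site counts against every candidate call. This makes
a missed call work against consensus, which reproduces the documented side
effect that majority-but-not-75% sites drop out of the truth set and then
score as false positives for the labs that did find them. The fraction
test uses integer cross-multiplication (`agree * den >= num * cover`), so
6/8 at 75% is inclusively exact and no floating-point boundary case exists.

Scoring happens inside `assessable ∩ ROI`. Four assessable-region policies
are provided: protein-coding exons extended by 2 bp (the two essential
splice bases); the same restricted to exons containing a consensus-variant
start; the exact reference spans of the truth variants (somatic, no
extension); and a per-lab pruning that removes ROI further than 1000 bp
from any variant the lab itself reported — a correction for grossly
over-declared ROIs. Each call then falls into Agree (TP), Disagree (FP and
FN), Extra (FP) or Missing (FN); germline matching compares the genotype
class (phasing ignored), somatic matching only the alternate allele. Only
SNVs and indels shorter than 50 bp are assessed; larger and symbolic events
are listed separately, not scored.

## Normalization

All comparisons run on canonical representations: multi-allelic records
are decomposed (other ALTs recoded as an "other non-ref" genotype marker;
alleles absent from the genotype are dropped at ingest and counted),
same-length substitutions are split into SNPs at mismatching offsets,
alleles are trimmed to minimal representation — shared suffix first, then
shared prefix, keeping the single VCF anchor base — and indels are
left-aligned against the reference. Suffix-before-prefix order matches
the dominant normalization convention so consensus keys are stable across
pipelines. Left alignment fetches reference context in doubling windows
(64 bp, 128 bp, ...) until the leftmost placement is provable, which
bounds reads on long homopolymers; the input REF is validated against the
context and refused on mismatch. Normalization is idempotent, and
equivalence is defined by alternate-haplotype identity (checked in the
tests by direct string surgery against a brute-force enumeration oracle).

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `min_participants` | 7 | labs | minimum ROI coverage for a votable site |
| `agreement_fraction` | 0.75 | fraction | exact-call agreement threshold, inclusive |
| `exon_extension_bp` | 2 | bp | essential splice bases around coding exons |
| `somatic_proximity_bp` | 1000 | bp | ROI pruning distance from reported variants |
| `indel_max_len` | 50 | bp | eligibility bound (exclusive) for scored indels |
| `consensus_genotype` | TRUE | — | include genotype class in germline vote keys |

Whether the historical schemes keyed germline consensus votes on genotype
is not documented; it is configurable and defaults to on, with the
accepted consequence that a het/hom split of the same allele can deny both
classes 75% and drop the site.

The disagreement convention is likewise ambiguous in prose ("Disagree
(FP, FN)"): by default a same-site wrong call increments both FP and FN;
`disagree = "fn_only"` counts it once, since the choice changes precision.
"Same site" means identical (chrom, normalized start, REF); a different
REF at the same start is extra+missing, not disagree.

In the 2016-style merged mode, the pre-established EQA truth is primary
and a differing *strong* consensus (≥ 7 covering, ≥ 75% agreement)
overrides it per site; EQA-only sites are kept as fall-back. The
fall-back's converse is undefined in the source material: sites present
only in a *weak* consensus are excluded here rather than guessed, and
reported in the `weak_excluded` attribute.

## The synthetic cohort: what it emulates, and what it does not

The generator states a world: uniform random chromosomes with homopolymer
and dinucleotide tracts planted every ~500 bp (so left-alignment is
genuinely exercised), 150 bp exon windows kept with probability
`exon_density`, and a truth set whose indel length distribution is
geometric with median 3 bp, capped at 35 bp — echoing the published shape
of a germline truth set (about 39 SNPs per indel, median 3 bp, max 35 bp).
Labs are profiles: an ROI fraction, Bernoulli per-variant miss rate,
Poisson spurious-call rate per kb, genotype-error rate, and probabilities
for three representation quirks (padded MNP records, right-shifted indels,
an extra uncalled multi-allelic artifact allele). A deterministic-drop
mode assigns each variant an exact set of missing labs, which makes the
75%-boundary and recovery tests exact rather than probabilistic.

The multi-allelic quirk deliberately leaves the genotype at 0/1 with an
uncalled artifact ALT: a 1/2 merge would change the genotype class and the
planted truth could then not be recovered by normalization alone, which
the recovery property requires.

What the generator does *not* emulate: read-level sequencing error (FASTQ
fixtures for the QC module are plain quality streams), mappability and
capture bias, FFPE artifacts, structural variants, multi-build cohorts. A
green recovery test therefore establishes the correctness of the voting,
normalization and scoring machinery — not the field performance of any
pipeline on real specimens.

## Numerical choices and degenerate inputs

- All internal coordinates are 0-based half-open; VCF's 1-based POS is
  converted at the I/O boundary only. Interval algebra is delegated to
  IRanges and results are always canonical (sorted, disjoint).
- `0/0` score ratios are defined as 0; undefined QC ratios (no homozygous
  calls, no transversions, no variants for the efficiency metric) are `NA`
  markers, never exceptions.
- FILTER `.` counts as PASS (many callers emit it for pass); switchable.
- Cohort percentiles use mean ranks, `(rank - 0.5)/n * 100`, so ties and
  singleton cohorts land at 50 by convention.
- Depth "uniformity" has no published definition; here it is the fraction
  of ROI bases with depth within a factor of two of the median ROI depth,
  and the choice is stated in the report.
- Validation never throws on malformed input: `validate_vcf()` returns a
  diagnostics table for arbitrary bytes (fuzz-tested), because
  submission-time feedback is part of the workflow.
- Complex substitutions (both alleles > 1 bp after trimming, lengths
  unequal) are compared as-is in class `complex`; whether the historical
  schemes decomposed them further is unknowable from the description.

## Known limitations

- The alignment-metrics module trusts per-read mismatch counts (the edit
  distance tag) instead of recomputing against the reference; this keeps
  it reference-free but inherits any aligner miscounting.
- Chromosome-name canonicalization handles the `chr` prefix dialect only.
- No gVCF reference blocks, BCF, tabix, or structural-variant semantics;
  symbolic ALTs are rejected with a diagnostic.
- GRCh37 and GRCh38 cohorts must be processed independently; there is no
  liftover.
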