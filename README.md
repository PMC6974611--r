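# ngseqa

Consensus truth sets and concordance scoring for external quality assessment
(EQA / proficiency testing) of clinical NGS laboratories.

## The problem

In an NGS proficiency-testing scheme, many laboratories sequence the same
reference material and submit the variants they called (a VCF) together with
the region of interest they claim to have analysed (a BED). The provider
must then decide, for every submission, which calls are right — without a
perfect external ground truth. `ngseqa` implements the computational engine
for such a scheme:

- **Participant consensus truth set** — a normalized call enters the truth
  set iff (a) its site lies in the declared ROI of at least
  `min_participants` labs (default 7) and (b) at least `agreement_fraction`
  (default 75%, compared with exact integer arithmetic so 6/8 counts) of
  those covering labs made the *identical* call. Covering labs that called
  nothing count against agreement.
- **Variant normalization** — multi-allelic decomposition, MNP→SNP
  splitting, minimal representation (suffix before prefix), and
  reference-guided indel left-alignment, so equivalent calls from different
  pipelines compare equal.
- **Assessable regions** — four policies: exons ±2 bp; consensus-containing
  exons ±2 bp; exact somatic variant spans; and per-lab pruning of ROI
  further than 1000 bp from any reported variant.
- **Concordance** — inside `assessable ∩ ROI`, each call is Agree (TP),
  Disagree (FP, FN), Extra (FP) or Missing (FN); germline matching requires
  the genotype class, somatic matching only the alternate allele; only SNVs
  and indels < 50 bp are assessed. Scores are

  sensitivity = TP/(TP+FN), precision = TP/(TP+FP),
  F = 2·P·S/(P+S).

- **QC metrics** — Q20/Q30 fractions and mean Phred from FASTQ; on/off
  target, error rate, 20×/30×/500× coverage, insert size, uniformity from a
  SAM-like alignment summary; Ti/Tv, SNP/indel counts, Het:Hom and call
  quality from the VCF — benchmarked as cohort percentiles.
- **Synthetic cohorts** — a deterministic generator for reference sequence
  (with repeat tracts), exon annotation, planted truth variants and labs
  with configurable FN/FP rates and representation quirks (padded MNPs,
  right-shifted indels, multi-allelic records), so everything above is
  testable offline.

## Worked example

The scheme's own validation of a consensus truth set against an independent
whole-genome call set produced TP = 21,161, FP = 1,127, FN = 224:

```r
library(ngseqa)
round(100 * compute_scores(21161, 1127, 224), 1)
#> sensitivity   precision     f_score
#>        99.0        94.9        96.9
```

A complete simulated EQA round:

```r
scaffold <- generate_reference(seed = 1, length_per_chrom = 50000L, exon_density = 0.3)
truth    <- plant_truth_variants(scaffold, n_snp = 300, n_indel = 20, scheme = "germline")
simulate_cohort(truth, n_labs = 10, lab_profile(quirk_rightshift = 0.5), seed = 1, dir = "cohort")
subs <- read_cohort("cohort/manifest.json", truth$sequences)
run  <- run_eqa(eqa_config("germline", "germline_exon2bp", subs,
                           exons = truth$exons, sequences = truth$sequences))
run
#> eqa_run: 10 lab(s), truth consensus with 320 variant(s)
#>    participant_id  TP FP FN sensitivity precision f_score region_bp
#> 1           lab01 320  0  0           1         1       1     14852
#> ...
#> F>0.80: 100%  F>0.95: 100%
```

Error-free labs recover the planted truth exactly (all F = 1); the printed
`region_bp` is each lab's `assessable ∩ ROI` size. `render_report(run,
"json"|"tsv"|"markdown", path)` writes the cohort report.

A command-line front end with `validate`, `simulate`, `consensus`, `assess`,
`metrics` and `run` subcommands is installed at
`system.file("cli/eqa.R", package = "ngseqa")`.

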