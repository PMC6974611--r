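Package: ngseqa
Title: Consensus Truth Sets and Concordance Scoring for NGS External
    Quality Assessment
Version: 0.1.0
Authors@R:
    person("EQA", "Informatics", email = "eqa@example.org", role = c("aut", "cre"))
Description: Computational engine for proficiency testing (external quality
    assessment) of clinical next-generation sequencing laboratories. Derives
    participant-consensus variant truth sets from many laboratories' VCF and
    BED submissions, constructs scheme-specific assessable regions, scores
    each submission's concordance (sensitivity, precision, F-score) under
    germline genotype-matching or somatic alternate-allele-matching rules,
    computes per-submission quality metrics (Ti/Tv, Het:Hom, Q20/Q30,
    coverage thresholds), and includes a synthetic cohort generator so the
    whole workflow is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
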