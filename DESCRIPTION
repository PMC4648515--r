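Package: StratDomFDR
Title: Stratified False Discovery Rates for Protein Domain Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stratified multiple-testing statistics for profile-HMM protein
    domain prediction. Estimates per-family (per-stratum) E-values, q-values
    and local false discovery rates from censored p-values, solves the
    equal-lFDR threshold optimization that maximizes predictions under a
    combined FDR or E-value budget, resolves overlapping domain predictions
    with clan and nesting awareness, computes empirical FDRs via clan-overlap
    and context-coherence labeling and via decoy (reversed or Markov-random)
    sequences, classifies domain families into noise classes by their
    empirical-FDR deviations, and supports two-tier (sequence then domain)
    q-value thresholds. Includes a fully ground-truthed synthetic data
    generator so every component is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
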