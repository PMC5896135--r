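Package: segscan
Title: Significance-Ranked Segmentation of Genomic Signal Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects the most statistically significant non-overlapping
    segments (regions whose mean differs from background) in long one
    dimensional genomic signal profiles, including signed tracks such as
    differential nuclease-sensitivity profiles and aCGH log-ratios. The
    scan combines a robust MAD-based noise estimate with prefix-sum
    dynamic programming over a geometric ladder of window lengths,
    greedy selection of non-overlapping candidates ranked by z-test
    p-value, boundary refinement by expansion and shrinkage, iterative
    merging of adjacent segments, Benjamini-Hochberg false discovery
    rate control, and effect-size ("biological cutoff") tiers. Includes
    a synthetic-profile generator with ground truth and bin-level
    precision/recall/F1 evaluation utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
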