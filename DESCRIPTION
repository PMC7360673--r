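Package: plvfc
Title: Phase-Locking-Value Functional Connectivity with Cluster-Based
    Permutation Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Source-space functional-connectivity analysis for resting-state
    electrophysiology. Computes band-limited phase-locking values (PLV)
    between sources on a regular MNI-like grid, reduces them to seed-based
    connectivity vectors and resting-state-network mean connectivity, and
    compares groups with independent-samples t-tests corrected by
    cluster-based Monte-Carlo permutation testing. Includes a synthetic
    coupled-oscillator cohort generator with a closed-form (Bessel-ratio)
    coupling oracle, clinical-table summaries (Fisher's exact test,
    Mann-Whitney U), and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
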