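Package: nipscnv
Title: Noninvasive Prenatal Screening of Fetal Aneuploidy and Microdeletions
    from Low-Coverage Maternal-Plasma Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Read-depth screening of maternal-plasma cell-free DNA for fetal
    whole-chromosome aneuploidies and pathogenic microdeletion syndromes
    (Williams-Beuren 7q11.23 as the flagship target). Implements
    mappability-quota genome windowing, per-sample GC-bias correction by
    cubic-spline fitting, same-lot per-window Z-scores, a three-state
    discrete-emission hidden Markov model for copy-number segmentation,
    syndrome-catalog matching with ISCN-style reporting, chromosome-Y
    fetal-fraction estimation with sample QC, and a synthetic-cohort
    simulator with ground-truth tables for desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
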