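Package: larcscore
Title: Response Scoring and Outcome Analysis for Neoadjuvant Rectal Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for scoring treatment response in locally advanced rectal
    cancer (LARC) cohorts treated with total neoadjuvant therapy: the
    immunoscore from CD3/CD8 T-cell density percentiles in tumor core and
    invasive margin, the pathologic and radiologic neoadjuvant rectal (NAR)
    scores with their low/intermediate/high categories, derivation of
    pathologic complete response endpoints from regression grades and nodal
    stage, exact contingency-table tests (Fisher and its Freeman-Halton
    generalization by full enumeration), Kaplan-Meier estimation and the
    log-rank test, deterministic reference fixtures reconstructed from
    published aggregate counts, a seeded synthetic cohort simulator, and an
    end-to-end analysis pipeline with CSV input/output and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
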