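Package: stressig
Title: Enhancer-Driven Gene Signature Discovery and Survival Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving stress-responsive enhancer gene signatures in
    pancreatic cancer and stratifying patient outcomes with them. Implements
    differential ChIP-seq/ATAC-seq peak intersection and the derivation of
    "STAT-open" regions (sites bound by activated STAT3 that are accessible only
    in inducible cell lines), enhancer-to-gene annotation, correlation-frequency
    gene selection, inducibility signatures from cell-line panels, rank-based and
    mean-expression signature scoring, Kaplan-Meier best-cutoff survival
    stratification, and single-cell extreme-decile stratification with
    treatment-enrichment estimation. A seeded synthetic-data generator plants
    ground truth for every stage so the full pipeline can be exercised and
    validated end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Matrix,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
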