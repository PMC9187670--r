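Package: tmadtools
Title: Shallow WGS Copy-Number Profiling, t-MAD ctDNA Scoring and Trial
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for quantifying circulating tumour DNA
    (ctDNA) from shallow whole-genome sequencing (sWGS) bin counts via the
    trimmed median absolute deviation (t-MAD) of segmented copy-number log2
    ratios. Provides GC/mappability bias correction, healthy-control
    normalisation, circular binary segmentation and Gaussian hidden Markov
    model segmentation with per-bin averaging, an empirical healthy-panel
    blacklist, response-group stratification with Wilcoxon rank-sum tests,
    exact binomial (Clopper-Pearson) confidence intervals and related
    clinical summaries, and a PCA-based overexpressed-gene signature
    assessment. A seeded synthetic-data generator produces binned read
    counts, multi-timepoint cohorts and expression matrices so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    cluster,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
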