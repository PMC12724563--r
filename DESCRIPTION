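Package: ectoactivity
Title: Transcription-Factor Activity Patterns Across a Developmental
    Stage by Cell-Type Grid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers transcription-factor (TF) downstream activity from
    single-cell RNA-seq log-fold-changes using a univariate linear model
    against a signed TF-target regulon network, and classifies activity
    patterns (quadrant, continuous, exclusive, gradient) across a grid of
    developmental stage by cell-type identities. Includes one-vs-rest
    Wilcoxon rank-sum differential expression, ATAC-seq motif-occupancy
    summary statistics, mass-action ligand-receptor communication scoring
    with permutation significance, and a synthetic-data generator that
    plants known regulatory truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
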