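Package: regevol
Title: Accessibility and Motif Determinants of Transcription Factor
    Binding Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A quantitative framework for relating interspecies changes in
    chromatin accessibility and motif presence to changes in transcription
    factor (TF) binding at orthologous enhancers, and for assessing those
    predictions through enhancer-activity models. Provides a thermodynamic
    position-weight-matrix occupancy model with a single fitted
    concentration parameter, support-vector-regression predictors of
    interspecies ChIP-score change from accessibility and motif features,
    accessibility-residual codivergence statistics, gradient-boosted
    enhancer-activity classifiers with synthetic minority oversampling,
    and an imputation-based agreement analysis with permutation controls.
    Includes a synthetic orthologous-enhancer cohort generator with
    ground-truth latents for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    e1071,
    xgboost,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
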