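Package: methylselex
Title: SELEX and Methyl-SELEX Analysis of Transcription-Factor Dimer
    Configurations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Downstream analysis of HT-SELEX and Methyl-SELEX experiments
    probing how cytosine methylation rewires transcription-factor binding,
    modelled on the homeodomain factor AtWOX14. Provides k-mer enrichment
    trajectories and enrichment-based mutual information (E-MI), seed-driven
    multinomial position weight matrix construction with exact dynamic-
    programming p-value thresholds, a half-site grammar that classifies
    dimeric binding sites into direct/inverted/everted repeats with spacing
    (DR/IR/ER), methyl-versus-normal positional motif comparison, and DAP-seq
    peak statistics (overlap tests, top-peak motif containment, peak-intensity
    contrasts). A generative SELEX simulator with an explicit binding model
    (monomer energies, spacing-dependent dimer cooperativity, methylation
    deltas) supplies ground-truth libraries so every stage of the pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
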