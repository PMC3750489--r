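Package: togaregulon
Title: Comparative-Genomics Reconstruction of Bacterial Sugar-Utilization Regulons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction of transcription-factor regulons across groups of
    related bacterial genomes, modelled on the comparative-genomics workflow
    used for the Thermotogales carbohydrate-utilization network. Provides
    genome and operon models with upstream-region extraction, Gibbs-sampling
    discovery of shared DNA motifs, additive position-weight-matrix scanning
    with a minimum-training-score threshold, cross-genome conservation
    filtering with iterative profile refinement, concordance checks of
    regulons against condition-specific expression (fold change and
    hypergeometric enrichment), a synthetic multi-genome community generator
    with planted sites for benchmarking, and a packaged catalog of the
    Thermotoga maritima sugar regulons with bookkeeping consistency checks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
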