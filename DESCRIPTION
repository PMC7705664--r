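Package: frostnet
Title: Coexpression Network Analysis of Cold-Stress Bark Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bulk RNA-seq experiments that profile chilling
    and freezing stress, modelled on dormant apple branch bark assayed across a
    stepped low-temperature schedule. Provides FPKM quantification and
    expressed-gene filtering, a conditional negative-binomial exact test for
    differential expression between chilling and freezing treatments with
    phase-pattern classification of the resulting gene sets, weighted gene
    coexpression network construction (soft thresholding, topological overlap,
    average-linkage module detection and eigengene-based merging), module
    eigengene, intramodular connectivity and trait-based gene significance
    analysis with a top-quantile intersection hub-gene screen, electrolyte
    leakage and accumulated-low-temperature phenotype helpers, relative qPCR
    quantification, hypergeometric gene-set enrichment, and a synthetic-data
    generator that emulates the two-cultivar seven-temperature design with
    planted coexpression modules and phase-patterned differential expression
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
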