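Package: florastage
Title: Multi-Stage Floral Transcriptome Analysis with RPKM, Fisher-Exact
    Differential Expression and Cross-Platform Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a classic single-library-per-stage
    RNA-seq analysis workflow for developmental series, modelled on floral
    transcriptome studies in Arabidopsis thaliana. Provides RPKM
    quantification from raw read counts, expressed-gene calling by a read
    threshold, pairwise differential expression with Fisher's exact test,
    per-gene Z-score stage-specificity profiles, fold-change based
    stage-specific gene detection, cross-platform (RNA-seq/EST/tiling
    array/microarray) expressed-gene consensus, protein-family detection
    and enrichment tables, and tandem gene-array detection. A negative
    binomial synthetic-data generator with planted stage-specific programs
    and family structure makes every step of the pipeline testable end to
    end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
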