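Package: expressome
Title: Integrative Transcriptome, Translatome and Proteome Analysis of
    Bacterial Stress Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building multi-layered expression maps of bacterial
    stress responses from two-color microarrays (total RNA and polysome
    fractions), heavy-standard SILAC proteomics, and strand-specific RNA-seq
    coverage.  Implements MA-value computation and within-array LOESS
    normalization, replicate combination with moderated statistics,
    heavy-standard SILAC ratio-of-ratios quantification with
    Benjamini-Hochberg correction, time-course k-means clustering and sigma
    factor regulon kinetics, pairwise cross-layer correlation and concordance
    classification, operon expression polarity calling, and proteogenomic
    discovery of unannotated open reading frames via six-frame translation
    and in-silico Lys-C digestion.  A fully specified synthetic-study
    generator with planted ground truth makes every stage testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    limma,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
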