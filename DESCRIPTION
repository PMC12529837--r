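Package: cftim
Title: Tissue-Informative CpG Markers and Tissue-of-Origin Deconvolution for
    Cell-Free DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for targeted cell-free DNA (cfDNA) methylation
    biomarker development. Selects tissue-informative CpG markers (TIMs) from
    multi-tissue whole-genome bisulfite sequencing reference panels, designs
    bisulfite-converted capture probe pairs, estimates per-sample
    tissue-of-origin proportions by expectation-maximization over binomial
    methylation read counts (with support for unknown tissue components),
    engineers methylation-proportion and normalized-coverage feature matrices,
    and fits penalized regression models with cross-model selection and
    averaging (CMSA) for disease classification, phenotype prediction, and
    epigenetic age acceleration. Ships a synthetic-data generator that emulates
    case/control cfDNA cohorts so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
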