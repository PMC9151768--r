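Package: editscape
Title: Cell-Type-Resolved A-to-I RNA Editing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying adenosine-to-inosine (A-to-I) RNA editing
    at cell-type resolution: de novo and supervised site calling from pileup
    tables with a multi-rule quality filter cascade, global editing indices
    (Alu editing index and normalized hyper-editing rate), hyper-editing
    detection by transformed alignment with cluster extension and merging,
    covariate-adjusted differential editing with cell-type specificity and
    enrichment classification, variance partitioning across biological and
    technical factors, pseudo-bulk validation of sites in single-nucleus
    pools, non-negative least squares cell-type deconvolution of bulk
    expression, and cis editing quantitative trait locus (edQTL) mapping.
    A synthetic-data module generates genomes, annotations, pileups, reads,
    genotypes and bulk mixtures with known ground truth so that every stage
    of the pipeline can be exercised and validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    Biostrings,
    pracma,
    lme4,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
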