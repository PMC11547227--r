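Package: ascitesProfiler
Title: Genomic Instability and Clonal Tracking from Ascites Cell-Free DNA
    Panel Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for targeted panel sequencing of cell-free DNA
    from ovarian cancer ascites. Provides somatic variant triage against
    population allele-frequency databases, tumour-purity estimation from a
    deleterious TP53 variant under the double-hit model (with a proportional
    fallback), purity-rescaled copy-number estimation with modified-Z segment
    repair, large-scale genomic alteration (LGA) counting, a 100-kb binned
    loss-of-heterozygosity (LOH) percentage with reliability guards, tumour
    mutation burden, a 0-3 above-median genomic-instability consensus score,
    longitudinal clonal-prevalence tracking across sequential ascites samples,
    and a synthetic-cohort simulator with full ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
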