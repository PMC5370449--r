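Package: methylDR
Title: Binned Differential Methylation Analysis of Aging and Dietary Restriction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of whole-genome bisulfite sequencing methylomes from
    aging cohorts under ad libitum and dietary-restricted feeding. Implements
    unbiased fixed-CpG-count sliding-window binning with coverage and
    high-observation filters, chi-squared calling of differentially methylated
    regions with Benjamini-Hochberg correction and a minimal-difference cutoff,
    detection of age-related methylation changes ameliorated by dietary
    restriction via regression-residual classification against permutation
    nulls, rule-based genomic and chromatin element catalogs with Fisher
    observed/expected enrichment, whole-gene-body differential methylation and
    methylation-expression coupling, and triglyceride acyl chain-length and
    saturation statistics. A seeded synthetic-data generator produces
    methylomes, annotations, expression and lipid tables with known ground
    truth so every stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics, Sequencing,
    Lipidomics, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
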