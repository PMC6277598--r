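Package: aseLandscape
Title: Allele-Specific Expression Analysis for Paired Tumor-Normal Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-wide allele-specific expression
    (ASE) analysis in paired tumor-normal cohorts: variant-level quality
    filters, a DNA-controlled binomial log-likelihood-ratio ASE test at SNV
    and gene level with a heterogeneity exclusion, sliding-window
    permutation detection of ASE hotspots with add-one-smoothed empirical
    p-values and Benjamini-Hochberg correction, classification of genes
    harboring allelically expressed somatic mutations by mutant-allele
    direction and expression fold change, and a Poisson excess-recurrence
    test for tumor-specific ("somatic") ASE genes. Includes a synthetic
    cohort generator with ground truth so every stage is testable without
    access to controlled patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
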