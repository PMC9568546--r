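Package: clonoscope
Title: Detection and Clonal Architecture of Radiation-Induced Clonal
    Hematopoiesis from Deep Sequencing Variant Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing recurrent somatic mutations in deeply
    sequenced mouse tissues to detect and characterise clonal hematopoiesis
    (CH). Implements variant-allele-frequency (VAF) candidate filtering,
    tissue-distribution classification of mutations into embryonic-mosaic
    and CH-associated groups, mutation-spectrum characterisation
    (pyrimidine-collapsed substitution classes, deletion lengths, junction
    microhomology, clustered multisite events), reconstruction of clonal
    architecture from single hematopoietic stem/progenitor cell colony
    genotypes (clone grouping, nesting and exclusivity, cell-fraction
    estimation by VAF doubling), group statistics (exact conditional
    Poisson rate comparison, weighted least squares with the Breusch-Pagan
    heteroskedasticity check), and a synthetic cohort generator with
    exported ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
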