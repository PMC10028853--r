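Package: drabr
Title: Differential Regulation Analysis by Bootstrapping
Version: 0.1.0
Authors@R: person(family = "drabr developers", role = c("aut", "cre"),
    email = "drabr@example.org")
Description: Gene-level tests of whether the cis-genetic regulation of
    expression differs between two biological contexts (tissues, cell types,
    disease states). Context-specific elastic-net models predicting
    expression from cis-SNP dosages are trained per context, and their
    population-level equivalence is tested with a bootstrap model-comparison
    test that accounts for the variability of feature selection and model
    training, alongside the classical conditional paired-t comparison.
    Includes PLINK BED/BIM/FAM input, variant quality control
    (Hardy-Weinberg mid-p, minor allele frequency), covariate
    residualization, genomic-control diagnostics, and a synthetic-cohort
    simulator for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    glmnet,
    stats
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
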