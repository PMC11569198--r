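Package: crossprs
Title: Cross-Disorder Polygenic Risk Score Pipeline for Schizophrenia and
    Bipolar Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quality control, polygenic scoring and association analysis for
    cross-disorder studies of schizophrenia (SCZ) and bipolar disorder (BPD).
    Implements genotype and sample quality control (call rate, minor allele
    frequency, Hardy-Weinberg exact test, heterozygosity outliers and
    PI-HAT-based relatedness pruning) with an auditable exclusion ledger;
    construction of eight polygenic risk scores including shared (SCZ+BPD),
    disorder-contrast (SCZ vs BPD) and sign-concordance split scores from
    GWAS summary-statistic weight files; and the downstream association
    model suite (logistic disease models with incremental Nagelkerke
    pseudo-R-squared, proportional-odds models for educational attainment,
    linear and logistic models for cognitive-aging outcomes).  A
    liability-threshold simulator generates genotypes, discovery summary
    statistics and phenotypes with a configurable shared/specific bivariate
    genetic architecture so the full pipeline can be exercised end-to-end
    on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
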