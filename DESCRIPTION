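Package: eqtlrep
Title: Cross-Study Discovery and Replication of Expression QTLs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-cohort cis/trans expression quantitative trait locus (eQTL)
    mapping and replication analysis. Implements single-SNP Bayesian-regression
    Bayes factors, demographic and surrogate-variable covariate adjustment with
    within-population inverse-normal transformation, Storey q-value FDR, genotype
    and expression quality control (exact Hardy-Weinberg test, call-rate and MAF
    filters, probe clustering into probesets, Dixon outlier screening, sex
    inference), probe-polymorphism hybridization-artifact annotation, a formal
    cross-panel replication criterion with concordance-based adjustments,
    demographically matched resampling baselines and winner's-curse diagnostics,
    logistic modelling of replication determinants, and mixed-model analysis of
    haplotype-specific reporter assays. Ships a multi-study synthetic data
    generator with known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml,
    vcfR,
    rtracklayer
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
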