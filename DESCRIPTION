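Package: resqtl
Title: Cognitive Resilience Scoring and Protein QTL Mapping for
    Recombinant Inbred Mouse Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cognitive resilience in recombinant inbred
    backcross mouse panels and tracing it to genetically regulated protein
    modules. Implements regression-residual resilience scoring of contextual
    fear memory against non-transgenic strain baselines, ANOVA-based
    heritability with the strain-mean (replicate-adjusted) correction,
    normalization and batch correction of peptide-level proteomics with
    peptide-to-protein roll-up, additive-model protein quantitative trait
    locus (pQTL) scans with Benjamini-Hochberg control and cis/trans
    classification, linkage-disequilibrium haplotype-block extraction,
    trait association and genotype-stratified moderated-t differential
    expression, principal-component mediation analysis of SNP -> module ->
    trait effects with bias-corrected accelerated bootstrap intervals, and
    intersection of haplotype SNPs with transcription-factor binding-site
    intervals. A calibrated synthetic-cohort generator with recorded ground
    truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    boot,
    optparse,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
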