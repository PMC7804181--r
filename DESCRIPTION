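Package: mlcbias
Title: Disease-Ascertainment Bias in Behavioural-Trait GWAS: Simulation and
    Misreport/Longitudinal-Change Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates biobank-style cohorts in which a disease ascertains a
    behavioural phenotype (affected individuals reduce the behaviour and may
    misreport it), and quantifies the downstream damage in genome-wide
    association studies and their follow-up analyses: spurious associations,
    loss of power, sign-flipped SNP-effect correlations, biased
    instrumental-variable causal estimates, and manufactured J-shaped risk
    curves. Implements a two-step correction: phenotypic quality control of
    suspected misreporters, then stratified association scans by self-reported
    longitudinal-change group combined by inverse-variance-weighted
    meta-analysis. Includes fast per-SNP least-squares scans, greedy LD
    clumping, an error-corrected SNP-effect-correlation estimator with
    jackknife standard errors, Wald/IVW/median Mendelian-randomisation
    estimators, binned odds-ratio risk curves with reference-group composition
    accounting, and a down-sampling test for excess loss of significant loci.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    metafor,
    ggplot2
Config/testthat/edition: 3
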