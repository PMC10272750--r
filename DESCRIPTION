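Package: twinherit
Title: Heritability of Serum Biomarkers from Classical Twin Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biometric variance-component analysis of quantitative serum
    biomarkers measured on monozygotic and dizygotic same-sex twin pairs.
    Fits the classical ACE, ADE, AE, CE and E models by maximum likelihood
    on bivariate-normal pair likelihoods, with optional age and sex
    adjustment in the mean model, broad-sense heritability with
    delta-method confidence intervals, nested likelihood-ratio tests and
    AIC model selection. Also provides zygosity-specific Pearson and
    maximum-likelihood intraclass correlations, cluster-robust descriptive
    statistics that treat twin pairs as sampling units, outlier and
    transformation sensitivity analyses, and a synthetic twin-cohort
    generator with a latent additive-genetic, dominance, shared- and
    unique-environment structure for testing the full pipeline when
    subject-level registry data cannot be shared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    sandwich,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
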