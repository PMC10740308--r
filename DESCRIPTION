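Package: twinomics
Title: Longitudinal Twin Multi-Omics Modelling of BMI Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for longitudinal twin multi-omics
    studies of body-mass-index trajectories. Provides a synthetic twin-cohort
    generator with known genetic architecture; proteomics/metabolomics-style
    preprocessing (log2 transform, missingness filtering, per-batch minimum
    imputation, empirical-Bayes batch adjustment, PCA outlier screening,
    z-scaling, probe-to-gene collapsing); latent growth curve models fitted by
    full-information maximum likelihood with fit indices, cluster-robust
    standard errors and regression factor scores; linear mixed-model
    association scans with Satterthwaite t-tests and Bonferroni control;
    classical twin variance decomposition (saturated, ACE/AE/CE/E with AIC
    selection, bivariate Cholesky AE genetic and environmental correlations);
    and covariate-residualized multi-omics correlation networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    sva
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
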