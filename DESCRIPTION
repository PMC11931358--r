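Package: rmstaug
Title: Augmented Restricted Mean Survival Time Tests and Blinded Sample
    Size Re-Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis of randomized clinical trials that use the
    difference in restricted mean survival time (RMST) as the treatment
    contrast. Implements the standard RMST-difference test with both the
    plug-in and martingale-score variance estimators, the covariate-augmented
    test whose coefficient is obtained by least-squares projection of the
    per-subject influence scores onto treatment-centered baseline covariates,
    a local asymptotic power formula that requires only the control-arm
    survival curve and the censoring distribution, design-stage sample-size
    calculation from reference data (including the covariate variance
    reduction e-squared and a stepwise covariate selection path), blinded
    mid-trial sample-size re-estimation from pooled data, and a simulation
    engine with Gaussian-copula covariate-dependent exponential and
    piecewise-exponential trial generators for operating-characteristics
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
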