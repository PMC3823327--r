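Package: prevconv
Title: Spatial Interpolation of Disease Prevalence by Discrete Process Convolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian small-area estimation of disease prevalence when
    prevalence counts are observed on one spatial framework (e.g., primary-care
    service areas) and estimates are required for another (e.g., residential
    neighbourhoods). Latent prevalence and risk-factor surfaces are represented
    as discrete process convolutions: kernel-weighted sums of random effects on
    a sparse regular grid. Collateral data streams sharpen the interpolation: a
    reflexive morbidity indicator (hospitalisation counts) observed on the
    target frame, and a formative ecological covariate (an air-quality index)
    observed only on the target frame and interpolated to the source frame by a
    second convolution process. Includes an adaptive Metropolis-within-Gibbs
    sampler, Brooks-Gelman-Rubin convergence diagnostics, stream-specific
    deviance information criteria for comparing kernel and process variants,
    posterior exceedance and cluster-centre classification of areas, and a
    synthetic-data generator reproducing the statistical structure of the
    motivating study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
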