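Package: mrirsp
Title: MRI-Only Mass Density and Proton Stopping-Power Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise estimation of material mass density and proton relative
    stopping power (RSP) directly from multi-sequence magnetic resonance images,
    for proton-therapy treatment planning research. Provides tissue-substitute
    phantom ground truth (elemental compositions, measured densities, RSP and
    mean excitation energies), supporting stopping-power physics (Bragg
    additivity, Bethe ratios, relative electron density, effective atomic
    number), a synthetic phantom-scene simulator producing per-sequence MR
    volumes and dual-energy-CT-style parametric maps with known ground truth,
    water-signal normalization and volume-of-interest voxel extraction, a
    fully connected neural-network regressor trained with Adam on mean squared
    error, dual-energy CT empirical conversion models and a single-channel
    linear-regression baseline, and per-phantom mean-absolute-percentage-error
    reporting with line profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
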