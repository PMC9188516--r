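Package: pmqmri
Title: Temperature Dependence and Correction of Post Mortem Quantitative Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for the temperature dependence of
    quantitative brain MRI parameters (T1, T2, T2*, mean diffusivity and
    fractional anisotropy) in in situ post mortem imaging. Provides a
    synthetic-data module that generates labeled brain phantoms and
    multi-contrast MRI signals (inversion-recovery spin-echo, multi-echo
    spin-echo and gradient-echo, diffusion tensor protocols) with Rician
    noise; voxel-wise relaxometry fits including a three-parameter
    inversion-recovery model with a B1-error inversion-efficiency factor;
    a log-linear diffusion tensor fit with MD/FA derivation; partial-volume
    exclusion and Otsu thresholding for region aggregation; and linear
    brain-temperature models with confidence intervals, adjusted R-squared
    and percentage-difference statistics, packaged together with published
    regression coefficients for temperature correction of post mortem maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
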