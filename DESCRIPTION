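Package: accubound
Title: Langevin Reconstruction and Integration-to-Bound Models for Neural Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven reconstruction of Langevin (drift-diffusion) equations
    from trial-epoched neural time series via binned Kramers-Moyal conditional
    moments with small-lag extrapolation, and integration-to-bound decision
    models built on the reconstructed equations. Includes a synthetic MEG-like
    epoch generator with known ground truth, Euler-Maruyama first-passage
    simulation, inverse-Gaussian (Wald) waiting-time fitting, threshold
    optimization against an empirical waiting-time target, L2 distances
    between fitted densities, and 1/f^alpha spectral-exponent estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
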