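Package: toxpatch
Title: Stochastic Two-Patch Population Dynamics Under Pulsed Toxicant Input
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a stochastic impulsive single-species population model on
    two patches in which periodically pulsed environmental toxicant drives both
    mortality and migration. Provides the exact piecewise-analytic solution of
    the impulsive toxicokinetic subsystem and its globally attracting periodic
    orbit, Ornstein-Uhlenbeck-derived time-varying growth and noise
    coefficients, closed-form survival thresholds (extinction, stochastic
    permanence, persistence in the mean, time-average lower bounds, p-moment
    bounds), and a positivity-preserving truncated Euler-Maruyama simulator
    with ensemble summaries and plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
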