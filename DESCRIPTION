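Package: wtastim
Title: Winner-Take-All Spiking Network Model of Pulsatile and Galvanic Microstimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a leaky integrate-and-fire winner-take-all attractor
    network performing a two-alternative perceptual decision task, with
    intracortical microstimulation delivered through a point-source electrode
    model (mirror-estimate coupling, amplitude-dependent pulse refractory
    gating, galvanic depolarizing block). Includes the full analysis suite:
    smoothed firing-rate estimation, psychometric fitting with non-parametric
    bootstrap, firing-rate trajectory statistics, population kurtosis time
    series, spike-timing statistics (phase locking, CV, pairwise synchrony),
    and a network-current index, together with reproducible canned experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    withr,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
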