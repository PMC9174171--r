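Package: phoscycle
Title: Global Abiotic Phosphorus-Cycle Box Model for Rocky Planets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A dynamical box model of abiotic phosphorus cycling between
    eight planetary reservoirs (atmosphere, oceans, continental and oceanic
    crust, marine sediments, upper and lower mantle, and an inert core).
    Directed fluxes -- extraterrestrial delivery, erosion, aeolian transport,
    sea spray, rain-out, subduction, continental accretion, arc/mid-ocean-ridge/
    hotspot volcanism, hydrothermal drawdown and mantle mixing -- are integrated
    with a fixed-step explicit scheme over 4.5 Ga, with saturation-capped
    "switchboard" reservoirs, randomized initial seeding, ensemble convergence
    diagnostics, and one-at-a-time parameter sensitivity sweeps. Results are
    returned as tidy tibbles with broom-style tidiers and ggplot2 plotting
    methods.
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
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
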