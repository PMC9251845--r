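Package: paratrap
Title: Individual-Based Simulation of Parasitoid Evolution on an
    Evolutionary-Trap Host
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic individual- and event-based simulation of a
    2-host/1-parasitoid system in which a novel, physiologically
    unsuitable host acts as an evolutionary trap. Hosts regenerate by a
    stochastic Ricker process with exponentially distributed vulnerable
    developmental periods; time-limited parasitoid females search
    patches, express a heritable host-preference trait and a heritable
    parasitization strategy (specialist on either host, or generalist
    with a developmental-rate cost), and their eggs race the host's
    sensitive period. Incompatible attacks either leave the host
    unharmed or kill it without producing parasitoid offspring
    (non-reproductive host mortality). The package exposes every model
    mechanism as a tested operation, runs replicated evolutionary
    experiments over parameter grids, and writes per-generation time
    series with provenance sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
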