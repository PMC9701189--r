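Package: oxfire
Title: Oxygen-Dependent Wildfire Flammability in a Reduced-Complexity
    Fire-Vegetation Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring how atmospheric oxygen concentration shapes
    wildfire activity and forest persistence. Implements empirically derived
    oxygen dependences of the probability of ignition, the moisture of
    extinction, and the heat of combustion, and routes them through a
    simplified SPITFIRE-style daily fire engine coupled to a minimal plant
    functional type (PFT) vegetation layer. A seedable synthetic-world
    generator supplies gridded daily weather and lightning forcing with
    realistic latitudinal structure, and an experiment driver runs oxygen
    sweeps (20.95 to 35 percent by volume) against a fire-off baseline,
    producing fire counts, burned area, tree cover, forest-suppression and
    rate-of-spread diagnostics as tidy tibbles with plotting and broom-style
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
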