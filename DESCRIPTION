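Package: pacweb
Title: Quantitative Plant-Herbivore Interaction Webs and the Potential
    for Apparent Competition
Version: 0.1.0
Authors@R:
    person("pacweb", "maintainers", email = "pacweb@example.org",
           role = c("aut", "cre"))
Description: Builds quantitative bipartite plant-herbivore interaction
    networks from long-format mesocosm survey data and computes the
    potential for apparent competition (PAC) between plants sharing
    herbivores, following the quantitative web approach of Muller et
    al. (1999). Includes standardisation of herbivore counts to dry
    biomass, experiment-wide meta-web construction and zero-filling of
    informative absences, species-level indices (normalised degree,
    leaf-damage index, herbivore:plant biomass ratios), a confidence
    interval test for exotic dominance of community biomass, a
    factorial mesocosm simulator for end-to-end testing without
    external data, and a reproducible pipeline driver with CSV schemas
    and input validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
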