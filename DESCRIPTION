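Package: critnat
Title: Mapping Critical Natural Assets on Gridded Landscapes
Version: 0.1.0
Authors@R:
    person("Critnat", "Developers", email = "critnat@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping critical natural assets: the minimum-area set
    of natural and semi-natural pixels that jointly maintain target levels of
    multiple nature's-contributions-to-people (NCP) surfaces. Provides a
    seeded synthetic-landscape generator, D8 hydrologic routing with
    downstream-beneficiary accounting, least-cost travel-time fields over
    friction surfaces, fourteen simplified NCP models with back-attribution
    of value to providing habitat, an exact and a greedy set-multicover
    prioritizer with accumulation curves and drop-one sensitivity,
    beneficiary delineation and counting, and overlap statistics against
    species habitat and language layers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    digest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
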