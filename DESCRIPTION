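Package: trawlcover
Title: Survey Footprints, Habitat Coverage and Density Tracking for
    Bottom Trawl Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how well scientific bottom trawl surveys
    cover the world's productive and fished continental shelves and the
    ranges of commercial demersal species.  Builds alpha-shape survey
    footprints from haul coordinates, classifies grid cells as productive
    shelf or trawl-fished habitat, computes coverage fractions and
    landings-weighted coverage with per-survey and data-availability
    breakdowns, determines how many surveys are needed to cover a target
    fraction of a species range (overlap count, greedy and exact set cover),
    and accounts for transboundary ranges and stocks across EEZ polygons.
    Includes a Poisson-link delta-gamma catch model with per-survey
    catchability and a low-rank spatial basis for combining heterogeneous
    surveys into yearly density surfaces and center-of-gravity tracks, and
    seeded synthetic-data generators (bathymetry, chlorophyll, effort,
    landings, habitat probability, haul point processes, catches) so the
    whole pipeline is testable without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
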