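Package: accesskit
Title: Interactive Travel-Time Scenario Modelling for Health-Service Access
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An open toolkit for raster-based travel-time and accessibility
    analysis of health services. Assembles a twelve-class land-cover grid from
    elevation (depression filling, D8 flow, Strahler stream ordering),
    vegetation and classed road data; converts land cover to per-cell
    friction surfaces under multi-modal travel scenarios (walking mode,
    time of day, weather, drawn barriers and roads, road-speed overrides);
    accumulates travel time to destination points with a 5x5 chamfer
    distance transform and an exact multi-source Dijkstra engine; classifies
    travel-time ('remoteness') zones; runs factorial scenario sweeps; and
    simulates individual patient journeys that combine off-road walking with
    opportunistic vehicle pickup on the road network. Includes a seeded
    synthetic-landscape generator so the full pipeline runs without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
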