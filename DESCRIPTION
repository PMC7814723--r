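Package: hfaccess
Title: Health-Facility Accessibility and Equity Analysis on Raster Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Country-scale geographic accessibility and equity analysis for
    tiered health-facility systems. Builds mode-specific friction (speed)
    surfaces from landcover, classed roads and protected-area barriers;
    computes least-cost travel-time rasters to the nearest eligible facility
    by multi-source Dijkstra on the 8-connected grid graph; tabulates
    population coverage within travel-time thresholds per facility tier with
    speed-uncertainty intervals; derives bicycle-versus-walking time-savings
    layers; detects high/low access clusters with the Getis-Ord Gi* statistic
    under cumulative queen contiguity of orders 1-3 and a monotone
    multi-order significance rule; and models access against poverty and
    population density with tuned random forests (permutation importance,
    partial dependence) and BIC-selected linear mixed-effects models.
    Includes a synthetic-landscape generator so the whole pipeline runs with
    known structure and no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    yaml,
    jsonlite,
    ranger,
    lme4,
    lmerTest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
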