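Package: trackmine
Title: Behavioral States, Co-Occurrence and Association Rule Mining for
    Animal Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fine-scale analysis of GPS-collar relocation data: residence-based
    classification of trajectories into behavioral states (rest, forage,
    transit), geodesic (Vincenty) proximity detection of spatiotemporal
    co-occurrence between animal pairs, from-scratch Apriori association rule
    mining with support, confidence, lift and phi interestingness measures,
    Cramer's V contingency validation, kernel utilization-distribution home
    ranges with isopleth overlap, categorical land-cover lookup, and a
    multi-state movement simulator that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    geosphere,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
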