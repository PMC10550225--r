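Package: seatag
Title: Dive Behavior, Subsurface Light Attenuation, and Bioenergetics from
    Archival Tag Records
Version: 0.1.0
Authors@R:
    person("seatag", "developers", email = "seatag@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing archival (data-storage) tag records from
    diving pelagic fishes: mixed layer depth estimation and dive extraction
    from depth-temperature time series, dive phase segmentation and U/V
    shape classification, midday light attenuation profiling from
    tag-measured irradiance with detection of deep attenuation increases
    consistent with acoustic scattering layers, a pluggable swimming-speed
    and temperature metabolic model with per-dive cost, cost rate and
    foraging profitability, hypothetical-dive cost comparisons, biome-level
    summaries with power-law temperature sensitivity, inverse distance
    weighted fields, and diel composites of shipboard acoustic backscatter.
    Includes a synthetic ocean-scenario and tag-record simulator with known
    ground truth so the full pipeline is testable without recovered tags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
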