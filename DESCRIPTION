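Package: mfbc
Title: Otolith Back-Calculation of Fish Length-at-Age with the Modified Fry Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs longitudinal length-at-age histories of reef fishes from
    otolith annulus radii using the modified Fry back-calculation model with a
    fitted allometric biological intercept, assembles the back-calculated
    observations into calendar-year age cohorts, and compares protected
    (marine-reserve) and fished populations with unbalanced two-way analyses of
    variance, a posteriori power analysis, and LOESS year-trend smoothers.
    Includes a von Bertalanffy based population simulator with known ground
    truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    car,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
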