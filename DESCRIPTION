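Package: osmolimit
Title: Diffusion-Limited Osmotrophic Growth of Phytoplankton Along Ocean Transects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the maximum growth rate that molecular diffusion of
    dissolved nitrogen and phosphorus can sustain for osmotrophic
    phytoplankton cells, from seawater physical chemistry (temperature- and
    salinity-dependent diffusion coefficients), imaged-cell morphology
    (equivalent spherical size, prolate and cylindrical shape factors) and
    allometric element quotas. Includes along-track interpolation of station
    nutrient fields, sea-surface-temperature region classification, critical
    cell-size limits at target growth rates, trophic-strategy summaries of
    diffusion-limited cells, a presence-absence endemism resampling null,
    and synthetic cruise/cell/occurrence generators for testing and
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
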