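Package: bioclimenv
Title: Bioclimatic Indices, Robust Climate Trends and Envelope-Based
    Habitat Suitability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the Rivas-Martinez worldwide bioclimatic
    classification parameters and indices (thermicity, ombrothermic,
    continentality and summer ombrothermic indices) from monthly weather
    station series, diagnoses isobioclimates (macrobioclimate, bioclimate,
    variant, thermotype, ombrotype and continentality horizons), projects
    station climate to a future year with an ensemble of robust linear
    trend estimators (ordinary least squares, Theil-Sen, Siegel repeated
    medians, Huber M and MM estimators), interpolates station indices onto
    regular grids, and maps rectilinear climate-envelope habitat
    suitability (min-max) and optimality (Q1-Q3) together with
    gain/unstable/stable change rasters. Includes a synthetic
    station-network and occurrence generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
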