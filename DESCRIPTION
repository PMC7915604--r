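Package: forestsep
Title: Band-by-Band Spectral Separability Analysis for Forest Type Discrimination
Version: 0.1.0
Authors@R:
    person("forestsep", "developers", email = "forestsep@example.org", role = c("aut", "cre"))
Description: Tools for pairwise spectral separability analysis of forest types
    from labeled reflectance cubes. Extracts per-class reflectance samples from
    polygons, computes four separability criteria (M-statistic, Bhattacharyya
    distance, Jeffries-Matusita distance, transformed divergence) for every band
    and class pair, selects best bands, and compares a hyperspectral against a
    multispectral sensor through percentage separability increments. Includes a
    synthetic two-sensor scene generator with known Gaussian class statistics so
    the whole pipeline can be validated without satellite downloads, plus
    ENVI-dialect raster and GeoJSON polygon input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
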