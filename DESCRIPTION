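Package: littoral
Title: Littoral Slope, Wind Exposure and Macrophyte Status Indices for Lakes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Transect-level analysis of how littoral slope and wind exposure
    shape lake macrophyte communities. Builds depth rasters from shoreline
    and isobath geometry, derives Horn-method slope rasters and per-transect
    shallow (Sl_1m) and deep (Sl_Cmax) littoral slopes, computes five-ray
    effective fetch and a wind-exposure index from multi-year hourly wind
    records via the Linear Directional Mean, calculates the Ecological State
    Macrophyte Index at lake (ESMI) and transect (ESMI_TR) level, and runs
    slope-class indicator species analysis (IndVal with permutation tests)
    and SIMPER decompositions. Ships a synthetic-lake generator with known
    ground truth (planar slopes, circular wind mixtures, trophic-gradient
    community matrices) so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
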