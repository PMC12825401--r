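Package: snowbloom
Title: Bio-Optics of Colored Snow Algae Blooms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the optical impact of red, orange and green
    snow algae blooms from field spectroradiometer reflectance (HDRF) spectra
    and per-sample biology tables. Implements band-range reflectance means,
    Sentinel-2A band-equivalent reflectances, the continuum-removal
    chlorophyll band depth at Band 4 (IB4), instantaneous radiative forcing
    over PAR and NIR windows with biomass normalisation, geometric cell
    biovolume, pigment signatures and astaxanthin:chlorophyll-a ratios, and
    the accompanying nonparametric group statistics. A seeded synthetic-data
    generator emulates clean-snow and bloom spectra together with matching
    cell-population and pigment tables so the full pipeline can be exercised
    and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
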