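Package: mipsense
Title: Digital Image Colorimetry and Adsorption Analytics for Molecularly
    Imprinted Polymer Plate Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies yellow azo dyes (tartrazine) captured on molecularly
    imprinted polymer (MIP) plates from smartphone photographs. Extracts mean
    region-of-interest colors, expands RGB into CMYK and HSV channels with the
    exact piecewise conversions used in digital image colorimetry, and builds
    a partial least squares (NIPALS) calibration with working-range selection,
    leave-one-out cross-validation and LOD/LOQ estimation. Also provides the
    full batch-adsorption toolbox for plate sorbents: removal percentage and
    areal capacity, linearized pseudo-first-order, pseudo-second-order and
    intraparticle-diffusion kinetic fits, Langmuir and Freundlich isotherms,
    imprinting and selectivity factors, and reusability profiling. A seeded
    synthetic plate-image and adsorption-data generator makes the entire
    pipeline testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    png,
    jpeg,
    jsonlite,
    yaml,
    withr,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
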