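Package: ropzone
Title: Schematic-Eye Modelling of Absolute ICROP Zone I Area in Retinopathy of Prematurity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Paraxial (Gaussian) two-element schematic-eye model of the neonatal
    eye that converts ocular biometry (corneal power, anterior chamber depth,
    lens power, lens thickness, axial length) into the absolute area of ICROP
    Zone I via the posterior nodal point and a 30-degree visual half-angle.
    Includes quadratic growth-curve fitting of ocular parameters against
    postmenstrual age, keratometric and Hoffer Q conversions, exhaustive
    combinatorial propagation of per-parameter candidate values to min/max
    Zone I area ranges, a seeded synthetic-data generator with fixtures
    anchored to published axial-length extremes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
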