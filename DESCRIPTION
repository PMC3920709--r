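Package: msepqsar
Title: Molecular Surface Electrostatic Potential Descriptors and QSAR Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes Politzer-style statistical descriptors of the molecular
    surface electrostatic potential (extrema, surface averages, the average
    deviation Pi, positive/negative variances and the balance parameter nu) on
    the 0.001 e/bohr^3 isodensity surface of an electron density supplied as a
    Gaussian cube file, and links them to biological activity through
    ordinary-least-squares QSAR regression with forward stepwise descriptor
    selection. Includes a Gaussian cube reader/writer, an isodensity surface
    extractor with analytic test oracles, an electrostatic potential evaluator
    from gridded densities plus point nuclei, and a packaged 15-compound
    pyrazine-2-carboxamide descriptor/activity table with reproduction helpers
    for the reference five-descriptor cytotoxicity model.
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
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
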