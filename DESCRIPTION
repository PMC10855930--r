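Package: hypersort
Title: Hyperspectral Wavelength Selection and Optical-Sorter Simulation for
    Gluten-Free Legume Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discriminating gluten-bearing cereal kernels (wheat,
    oat) from legumes (broad bean, chickpea, lentil) in hyperspectral
    reflectance imagery. Implements flat-field reflectance calibration from
    dark and white reference frames, ENVI cube input/output, background
    removal and per-seed mean-spectrum extraction, minimum-redundancy
    maximum-relevance (mRMR) wavelength selection driven by a
    mutual-information quotient with a forward-addition wrapper stopping
    rule, linear maximum-margin classification with a zero-false-positive
    operating point, and a stream simulation of an industrial optical sorter
    with broadband (15 nm) deployment, replicated runs and across-run
    ANOVA/Tukey comparison. A synthetic hyperspectral scene and seed-stream
    generator with planted discriminative bands makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
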