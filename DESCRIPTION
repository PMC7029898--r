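Package: hairsem
Title: Quantitative Hair Cuticle Damage Scoring from SEM Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated analysis of 8-bit greyscale scanning electron
    micrographs of single hair segments for quantitative scoring of cuticle
    surface damage. Provides region-of-interest extraction from user-supplied
    axis and diagonal line annotations, row-wise brightness normalization
    centred at a dark-grey reference value, three pixel-brightness damage
    metrics (mean brightness, polyline roughness, and the histogram tailing
    factor adapted from chromatographic peak-shape analysis), k-nearest
    neighbour damage grading against an ordinal cuticle damage scale, and a
    seeded synthetic micrograph generator so the whole pipeline can be
    exercised without real SEM data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
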