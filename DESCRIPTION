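Package: pilosity
Title: Quantifying Insect Pollinator Hairiness from Specimen Images via
    Local Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures the hairiness (pilosity) of insect pollinators from
    photographs of pinned specimens. Polygonal regions of interest (face,
    thorax dorsal, ...) are rasterized onto the image, pollen grains and
    other near-circular artifacts are segmented and excluded, and a local
    Shannon entropy filter with a disk-shaped radius of influence is run
    over each colour channel; the per-pixel product of the three channel
    entropies is summarized as a per-region mean and standard deviation,
    the hairiness trait value. A companion statistics layer performs
    exhaustive ordinary-least-squares model enumeration over region
    entropies with small-sample-corrected Akaike information criterion
    (AICc) ranking, Akaike weights, adjusted R-squared and variance
    inflation factors, linking hairiness to single-visit pollen deposition
    and pollen load. A synthetic-specimen generator with known ground
    truth supports testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1),
    methods
Imports:
    stats,
    utils,
    jsonlite,
    EBImage,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    png,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
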