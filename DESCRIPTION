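Package: entrast
Title: Information-Theoretic Heterogeneity Indices on Raster Grids
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes spectral heterogeneity maps from raster grids using
    information-theoretic diversity indices evaluated over a moving (focal)
    window: Shannon entropy, the Renyi generalized-entropy profile, Hill
    numbers, Simpson dominance and Rao's quadratic entropy (single- and
    multi-layer, with pairwise spectral distances). Includes the standard
    remote-sensing pre-processing steps (NDVI from red/near-infrared bands,
    8-bit radiometric rescaling), deterministic synthetic-raster generators
    for testing without satellite downloads, plain-text ESRI ASCII grid
    input/output, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
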