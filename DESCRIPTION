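Package: segfuse
Title: Fusion of Multiple 2D Binary Segmentations into a Consensus Contour
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Combines two or more binary segmentations of the same 2D object
    into a single consensus contour drawn as a closed, one-pixel-wide line.
    Implements eight fusion algorithms (Largest, Smallest, Average Smallest
    And Largest, three Average-Target variants, Middle with configurable
    tiebreak, and binary STAPLE expectation-maximization), three one-pixel
    line-extraction modes (internal, middle/skeleton, external), four methods
    for closing sparse contour points (linear and shape-preserving PCHIP
    interpolation in polar coordinates, morphological Chan-Vese and geodesic
    active contours), Jaccard-index evaluation with multi-algorithm ranking
    tables, and a synthetic rater simulator (radial boundary perturbation and
    per-pixel sensitivity/specificity corruption) for fully reproducible
    testing. A command-line interface covers fusion, evaluation, ranking,
    and fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    tiff,
    pracma,
    yaml,
    optparse,
    withr,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
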