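Package: zifnn
Title: Ensemble Micro Neural Networks for Designing Cys2-His2 Zinc Finger Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts optimal three-finger Cys2-His2 zinc finger proteins
    (ZFPs) for arbitrary 9 bp DNA targets. Implements representative sampling
    of the 4^9 DNA target space by seeded K-means clustering, enumeration of
    recognition-helix libraries by mutating the key alpha-helical positions
    (-1, +3, +6) of the Zif-268 template, hydrogen-bond free-energy scoring of
    candidate protein-DNA complexes, and an ensemble of 100 single-hidden-layer
    micro neural networks whose position-wise votes yield a consensus design,
    exact top-k predictions and an exponential confidence score. Includes
    Hamming-identity evaluation utilities and a synthetic-data generator
    emulating a deterministic (optionally synergistic) recognition code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
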