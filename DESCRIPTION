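Package: locanmf
Title: Localized Semi-Nonnegative Matrix Factorization for Widefield
    Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes widefield calcium imaging videos into spatial and
    temporal components that are anchored to the regions of a brain atlas.
    A semi-nonnegative matrix factorization is fit by hierarchical
    alternating least squares in a low-rank temporal subspace (LQ
    decomposition of the temporal factor), with an atlas-distance penalty
    that keeps each spatial component localized to its region. Per-region
    component counts and penalty multipliers are tuned automatically from
    two interpretable thresholds (region R-squared and component
    localization). Includes truncated-SVD video compression, low-rank
    hemodynamic correction and delta-F-over-F, a ground-truthed simulation
    generator, a vanilla semi-NMF baseline, and cross-session comparison
    tools (greedy component matching, canonical-correlation region maps).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    EBImage,
    tiff,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
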