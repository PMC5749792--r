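Package: georeg
Title: Feature-Based Image Registration with Geometric-Invariant Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Registration of 2-D grayscale image pairs through scale-adaptive
    binary local features and geometric-invariant point-set matching. Provides
    FAST-9 corner detection with Harris response selection and intensity-centroid
    orientation, steered 256-bit BRIEF descriptors with sub-window integration,
    an image-pyramid scale-ratio histogram filter, mean-centered Hamming distance
    window and bidirectional K-nearest-neighbour ratio screening, a distance-profile
    matcher that pairs keypoints by the geometric invariance of their inter-point
    distance vectors, and progressive sample consensus (PROSAC) estimation of the
    similarity transform. Includes deterministic synthetic fixture generators
    (textured scenes, low-texture star fields, labelled point correspondences)
    so every stage is verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, Visualization, Alignment
RoxygenNote: 7.3.3
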