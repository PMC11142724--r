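Package: elastrack
Title: Semi-Supervised Keypoint Tracking by Deformable Image Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks a fixed set of annotated keypoints through 2D/3D
    fluorescence videos by gradient-descent minimization of a four-term
    loss: local image-descriptor registration, a covariance-weighted
    elastic spring network between neighboring keypoints, proximity to an
    identity-blind feature-detection probability map, and temporal
    intensity smoothness. Reference frames are recommended by k-medoids
    clustering of frame thumbnails, remaining frames are sorted into
    similarity- or chronology-ordered parent-child branches with
    distance-scaled learning rates, and partial manual annotations are
    used both to pin keypoints and to interpolate a flow field that
    initializes the rest. Includes a deformable sparse-blob movie
    generator with ground-truth tracks, tracking evaluation (accuracy,
    RMS precision), and ratiometric fluorescence trace extraction with
    double-exponential photobleach correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
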