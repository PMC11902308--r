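Package: metagait
Title: Meta-Transfer Learning for Multimodal Lower-Limb Joint-Angle Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates lower-limb joint-angle trajectories from synchronized
    multimodal gait recordings (an RGB image stream, six-channel surface
    electromyography and visual-inertial odometry of the pelvis) with a
    meta-transfer learning pipeline: per-modality encoders (a CBAM-ResNet12
    image backbone and transformer sequence encoders), knowledge-sharing
    feature alignment across modalities, a three-branch convolutional fusion
    network with a joint-angle decoder, and few-shot intra-subject adaptation
    through multiplicative/additive parameter modulation trained episodically.
    Ships a subject-specific multi-rate synthetic gait simulator so the whole
    pipeline is trainable and testable without access to motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
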