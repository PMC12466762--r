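Package: bovimetry
Title: Non-Contact Cattle Body Measurement from Aligned RGB-D Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating cattle body traits (withers height, hip
    height, body length, cannon circumference) from a single pixel-aligned
    RGB-D side view. Provides hole filling of depth maps by the mean of the
    16 peripheral pixels of a 5x5 window, pinhole back-projection of
    anatomical keypoints into metric 3D coordinates, pass-through filtering
    of point clouds, ground-plane referencing from hoof-adjacent regions,
    object-keypoint-similarity (OKS) based evaluation of keypoint
    predictions, forward-pass implementations of the CASimAM, multi-head
    self-attention and DRAMiTransformer feature-map operators, and a
    ray-cast synthetic quadruped phantom with exactly known landmark
    geometry for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
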