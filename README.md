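# bovimetry

Non-contact estimation of cattle body traits from a single pixel-aligned
RGB-D side view.

Manual body measurement of cattle is slow, labor-intensive and stressful
for the animal. Given an aligned color + depth image of a standing animal,
the camera intrinsics, and six lateral anatomical landmarks (from an
annotation file or any keypoint detector), `bovimetry` computes four traits
used in breeding and health monitoring: **withers height**, **hip height**,
**body length** and **cannon circumference**, all in centimeters. It is
aimed at precision-livestock researchers who want a transparent, fully
testable measurement back end behind whatever keypoint detector they use.

## Method

For a landmark at pixel `(u, v)` with depth `Z` (meters), the inverse
pinhole model gives camera coordinates

    X = (u - cx) Z / fx,   Y = (v - cy) Z / fy,   Z = Z

with default intrinsics `fx = fy = 525`, `cx = 319.5`, `cy = 239.5`
(848x480 RGB-D sensor). Before lookup, missing depth pixels (`D = 0`) are
filled with the arithmetic mean of the valid values among the 16 pixels on
the outer ring of the 5x5 window centered on the hole; passes repeat
(Jacobi-style, scan-order independent) until stable. The scene cloud is
cleaned with a pass-through filter keeping `Z` in the open interval
`(z1, z2) = (0.1, 5)` m, then transformed to the world frame by a rigid
`p_w = R p_c + T`. The ground elevation `z0` is the median height of
cloud points near the hooves (lower half of the neighborhood, rejecting
limb points). Traits:

* withers / hip height = (landmark height − `z0`) x 100
* body length = 3D Euclidean distance between shoulder point and pin bone
* cannon circumference = pi x distance between the bilateral cannon
  landmarks (circular cross-section convention)

Keypoint predictions are scored with object keypoint similarity,

    OKS = sum_i exp(-d_i^2 / (2 s^2 sigma_i^2)) delta(v_i > 0) / sum_i delta(v_i > 0)

with threshold-grid AP (fraction of instances with OKS strictly above the
threshold), mAP, precision and recall. Forward passes of three
pose-detector attention operators (SimAM + coordinate attention =
CASimAM, multi-head self-attention, and a dual-branch spatial/channel
reciprocal transformer block) are included as shape-preserving array
operators with their detector insertion points.

Because no public RGB-D cattle data exist, the package ships a ray-cast
**synthetic phantom**: a parametric quadruped of exactly known dimensions
rendered into an aligned RGB-D frame with configurable depth dropout and
noise, so every stage is validated against analytic ground truth.

## Worked example

```r
library(bovimetry)

spec <- phantom_spec(withers_height_m = 1.30, hip_height_m = 1.34,
                     body_length_m = 1.60, cannon_diameter_m = 0.07,
                     camera_distance_m = 1.9)
ph <- render_phantom(spec)
m  <- measure_animal(ph$frame, ph$keypoints, ph$extrinsics)
print(m)
#> Body measurements (cm):
#>   withers_height_cm         130.00
#>   hip_height_cm             134.00
#>   body_length_cm            160.00
#>   cannon_circumference_cm    21.99
```

The phantom was built with those exact dimensions, so the printed values
are the analytic ground truth recovered end to end (21.99 = pi x 7 cm).
With 10 % depth dropout and 5 mm depth noise the same chain stays within
about 2 % on every trait. The same pipeline runs from the shell:

```sh
inst/cli/bovimetry synth --out ph/ --seed 3
inst/cli/bovimetry measure --manifest manifest.csv --report report.csv
inst/cli/bovimetry eval --pred pred.json --gt gt.json --out summary.json
```

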