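---
title: "Measuring cattle body traits from RGB-D side views: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cattle body traits from RGB-D side views}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovimetry)
```

## The measurement problem

A single RGB-D camera placed beside a standing animal yields a color image
and a pixel-aligned range map. Six anatomical landmarks visible in the
lateral view — top of the withers, top of the back at the hip, point of the
shoulder, posterior edge of the pin bone, and the two bilateral surface
points at the narrowest section of the forelimb cannon — are enough to
define four body traits: withers height, hip height, body length and
cannon circumference. `bovimetry` turns landmark pixels plus depth into
those traits, and quantifies how well a keypoint detector localizes the
landmarks in the first place.

This vignette records the package's own account of the method: the model
at each stage, the tunable parameters with their defaults and units, what
the synthetic phantom does and does not emulate, the numerical choices,
and the limitations we know about.

## Depth completion

Range maps from structured-light/stereo sensors contain zeros where no
measurement succeeded (specular hide, occlusion boundaries, sunlight).
`complete_depth()` fills a missing pixel with the arithmetic mean of the
valid values among the 16 pixels of the outer ring of the 5x5 window
centred on it.

Three numerical choices matter:

* **Jacobi passes.** All fills of one pass are computed from the pre-pass
  map, so the result is independent of pixel scan order — a property the
  test suite verifies by transpose symmetry and against a brute-force
  implementation that enumerates the 16 ring offsets explicitly. A single
  pass is the strict ring-mean operator; `max_passes` (default 5) repeats
  it so that hole blobs wider than the ring (for example the gap between
  the front and hind limbs) close from the rim inward.
* **Border clipping.** Within two pixels of the image border the ring is
  clipped to in-image positions and the mean uses what remains.
* **Validity.** "Valid" means strictly positive; `NaN` is coerced to 0 on
  ingest. Sky or out-of-range pixels that never had a measurement simply
  stay 0 if their whole ring is empty, and the function reports how many
  remain unfilled.

## From pixels to traits

**Back-projection.** The inverse pinhole model maps `(u, v, Z)` to camera
coordinates; the forward model projects back. Round-tripping is exact to
well below 1e-9 px, which the acceptance suite measures. Keypoints keep
their subpixel coordinates for back-projection; rounding happens only when
indexing the depth map.

**Keypoint depth lookup.** The depth assigned to a landmark is the median
of valid depths in the 3x3 window around its rounded pixel. We first used
the single center pixel with a 5x5 median only as a missing-value
fallback, but a single sample is fragile in exactly the worst place: the
cannon pair. The cannon is the smallest trait (~7 cm), and its landmarks
sit at silhouette edges where a half-pixel of rounding can land on a
grazing surface or a noisy sample; depth error enters the lateral
coordinate as `(u - cx)/fx * dZ`. A 3x3 median equals the surface depth on
any locally fronto-parallel patch (so the noiseless recovery below stays
exact) while cutting single-pixel noise roughly in half; in the degraded
phantom runs it brings the cannon error from ~2.2 % down to ~1.3 %. If the
center pixel itself was missing the lookup is flagged `depth_interpolated`;
if the whole 3x3 window is empty, a 5x5 median is the last resort before
declaring the landmark unmeasurable.

**Pass-through filter.** Points with `Z` outside the open interval
`(z1, z2)` are discarded; defaults `z1 = 0.1` m (sensor minimum) and
`z2 = 5` m (beyond any plausible stall geometry). The interval is open at
both ends — a point at exactly 5 m is removed — and kept + removed always
equals the input size.

**World frame and ground plane.** A rigid `p_w = R p_c + T` moves the
cloud to a world frame whose third axis is "up"; with the default
extrinsics the camera's `-y` becomes up and the camera sits at height
`camera_height` (0.8 m default) above the ground. Heights are coordinate
differences along the up axis, not point-to-plane distances along an
estimated normal — identical for a level floor, and simpler to reason
about. The ground elevation is estimated from "hoof-adjacent" points:
candidates within `radius` (0.15 m default) of a hoof hint, upper half by
height discarded to reject limb points, median of the rest; at least
`min_support` (50) candidates are required. Hints can be supplied
explicitly; otherwise `measure_animal()` derives them under the cannon and
body-end landmarks from the lowest cloud points in a horizontal disc.
Median-based estimation makes the result invariant to duplicated floor
points and robust to moderate limb contamination.

**Traits.** Heights are `(landmark height - z0) x 100` cm. Body length is
the 3D Euclidean distance between the shoulder point and pin bone. Cannon
circumference treats the distance between the bilateral cannon landmarks
as the diameter of a circular cross-section: `pi * d`. No elliptical
correction is applied. A landmark that is invisible, or has no valid depth
anywhere near it, removes only the traits that need it; the per-trait
`flags` record every fallback taken.

## OKS evaluation

`oks()` implements the standard object keypoint similarity: a Gaussian
similarity per visible ground-truth landmark with scale
`s^2 sigma_i^2`, averaged over visible landmarks. Two conventions needed a
decision:

* **Object scale.** The dimensionally consistent choice is
  `s = sqrt(bbox_area)`, which is the default (`sqrt_area`). A literal
  `raw_area` mode (squaring the area itself) is provided for comparison
  with formulations that write the area directly into the exponent.
* **Per-landmark sigmas.** No published constants exist for these six
  cattle landmarks, so all default to 0.05 — mid-range between the human
  COCO extremes — and are configurable per landmark.

`ap_at_threshold()` is the indicator form: the fraction of instances whose
OKS *strictly* exceeds the threshold. It is deliberately not the COCO
precision-recall-curve AP; ties at the threshold do not count, and AP is
non-increasing in the threshold (property-tested). `mean_ap()` averages
over the 0.50:0.05:0.95 grid or over categories.

`match_predictions()` pairs predictions with ground truth greedily in
descending confidence by highest OKS. Greedy matching can differ from the
globally optimal assignment when instances overlap heavily; in the
single-animal-per-frame regime this tool targets, instances are well
separated and the two coincide, which is how the equivalence test
constructs its scenes.

A note on jitter calibration: for Gaussian pixel noise with standard
deviation `sd` per axis, the *expected* OKS of a single landmark is
`1 / (1 + sd^2 / (s sigma)^2)` — at `sd = s sigma` (so `E[d^2] = 2 s^2
sigma^2`) the mean OKS is 0.5, not `exp(-1)`, because the mean of the
exponential is not the exponential of the mean. The `exp(-1)` operating
point is realized by the `ring` jitter mode of `perturb_keypoints()`,
which fixes the displacement radius at `sqrt(2) s sigma` exactly; the
Monte-Carlo acceptance check uses that calibrated mode.

## Attention operators

Three feature-map operators used by lightweight pose detectors are
provided as forward passes on plain `(batch, channels, height, width)`
arrays, with seeded weight initializers instead of a deep-learning
runtime — enough to verify shapes, parameter counts and algebraic
contracts without training:

* **SimAM** (zero parameters): per-channel closed-form energy from the
  channel mean and variance with regularizer `lambda` (default 1e-4);
  gate = `sigmoid((x - mu)^2 / (4 (var + lambda)) + 1/2)`. A constant
  channel gets a uniform gate, and the parameter census is asserted to be
  exactly zero.
* **Coordinate attention**: average pooling separately along height and
  width, a shared squeeze projection (`reduction`, default 8), and
  per-row/per-column sigmoid gates. **CASimAM** is the composition
  coordinate-attention(SimAM(x)), in that order, intended for the
  detector backbone.
* **MHSA**: scaled dot-product attention over flattened positions with
  `num_heads` heads (channels divisible by heads), concatenated and
  linearly fused; attention rows sum to 1. Intended insertion: before the
  detection head, as the attention stage of an MHSA-C2f block.
* **Dual-branch reciprocal transformer**: a spatial-attention branch and a
  channel-attention (transposed) branch computed in parallel, mixed by a
  learned per-channel sigmoid gate, followed by a two-layer FFN with a
  residual connection. Saturating the gate reduces the block to one
  branch plus the FFN path, which the tests exercise. Intended insertion:
  layer 15, right after the C2f block on the P3 (stride-8) feature map.

Default widths (64 channels, 4 heads) match P3-level widths of a
nano-scale detector. `write_block_config()` exports the three insertion
points as a YAML fragment. Full network assembly, training, and pretrained
weights are out of scope.

## The synthetic phantom

`render_phantom()` ray-casts a parametric quadruped: two axis-aligned
trunk boxes (front section topped at the withers height, rear at the hip
height), four vertical legs, and a bounded ground plane at height 0,
viewed by the default intrinsics from `camera_distance_m` away. Landmarks
are placed at analytically known surface points and projected to subpixel
pixel coordinates, so the returned trait ground truth equals the
specification by construction. Dropout zeros a seeded random subset of
valid pixels; noise adds seeded Gaussian perturbation; a `structured`
hole mode cuts a contiguous blob between the limbs for multi-pass
completion tests. Identical spec + seed gives bit-identical output.

Geometry choices worth knowing:

* **Legs are square prisms**, not cylinders, with cross-section side equal
  to the cannon diameter and the landmark pair on the camera-facing face.
  On a cylinder the bilateral landmarks are silhouette tangent points
  whose depth is never sampled at a pixel center, which biases the
  recovered diameter by construction rather than by any pipeline defect;
  the prism realizes the same diameter convention with well-defined
  surface depth. The far leg pair is staggered 0.12 m along the body so
  that rays grazing a near-leg edge do not land on the far leg.
* **Camera distance.** The sensor model's vertical field of view is
  about +/-24.5 deg (`fy = 525`, 480 rows). A 0-to-1.5 m tall scene *plus*
  the hoof-adjacent ground cannot fit through that aperture at the nominal
  1.5 m capture distance; real captures compose the shot accordingly. The
  spec default stays at 1.5 m, `render_phantom()` raises a visibility
  error with advice when landmarks leave the frustum, and the recovery
  studies run at 1.9 m with camera height 0.8 m, where the full trait
  range (withers 1.24-1.48 m) and the ground are simultaneously visible.
* **Secondary shape parameters** (trunk width 0.35 m, belly height
  0.60 m, cannon landmark height 0.22 m) are fixed plausible cattle
  proportions; traits do not depend on them beyond visibility.

What the phantom does *not* emulate: cattle texture and shading,
non-planar ground, posture variation, fur and specular depth artifacts,
multi-animal scenes, and detector-induced landmark error (keypoints are
either exact or explicitly jittered). Passing the recovery suite therefore
demonstrates the correctness of the geometry/measurement chain, not
field performance of any detector.

## Problem sizes and determinism

The recovery study uses 20 seeded specifications spanning withers heights
1.24-1.48 m, body lengths 1.39-1.78 m and cannon girths 18-24 cm, each
rendered at the full 848x480 resolution, clean and with 10 % dropout plus
5 mm depth noise. Mean absolute relative errors are ~0 (clean heights and
length), ~0.6 % (clean cannon, silhouette-edge rounding), ~0.1 %
(degraded heights/length) and ~1.3 % (degraded cannon). The Monte-Carlo
OKS calibration uses 10 000 draws. Unit tests run a half-resolution
phantom (scaled intrinsics) for speed; only the acceptance properties use
the full sensor geometry. All randomness flows through explicit seeds, and
package functions restore the caller's RNG state.

## Known limitations

* Heights assume a level floor; on sloped ground the coordinate-difference
  convention and a true point-to-plane distance diverge.
* The cannon circumference inherits the circular cross-section assumption;
  real cannons are mildly elliptical, so the convention systematically
  understates girth measured by tape.
* The greedy matcher is not a globally optimal assignment for crowded
  scenes.
* `relative_error()` reports |pred - gt| / gt on single values; averaging
  repeated measurements before or after the ratio gives slightly different
  summaries, so published per-animal tables computed over raw repeats may
  differ in the second decimal from what the printed averages reproduce.
* Depth maps are written as 16-bit TIFF (millimeters) because the R PNG
  writer is 8-bit only; 16-bit PNG depth is fully supported on read.
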