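---
title: "Edge-aware multi-view stereo for plants: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-aware multi-view stereo for plants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafmvs)
```

## The problem

Multi-view stereo (MVS) reconstructs 3D geometry from overlapping calibrated
photographs. Plants are a hard case: leaves are thin, rippled and mutually
occluding, and the depth signal is discontinuous exactly at leaf edges —
where depth networks make their largest errors, and where errors matter most
for traits such as leaf area. `leafmvs` implements the computational
machinery of an edge-aware MVS pipeline: the edge-augmented inputs and
losses used to train an edge-aware depth network, the geometric-consistency
fusion that turns per-view depth maps into a point cloud, and the complete
evaluation protocol for depth maps, point clouds and phenotypes. Depth
*inference* itself (the network) is deliberately outside the package:
predicted depth maps are inputs.

## Geometry conventions

All coordinates are metric (millimetres). A `camera_view` stores a
world-to-camera rigid transform (the MVSNet `cam.txt` convention, so files
load without inversion) and a zero-skew pinhole intrinsic. Pixel coordinates
are 0-based with **pixel centers at integer coordinates**: pixel (0, 0) is
the ray through `K⁻¹ (0, 0, 1)ᵀ`. The source publication of the `cam.txt`
format does not pin down either convention; these are declared once here and
used everywhere (projection, rendering, fusion, CLI). Depth is camera-frame
z. `project()` and `backproject()` are exact inverses to better than 1e-6
relative error over the working depth range, which the test suite asserts.

Depth maps serialize as PFM (little-endian, bottom-up scanlines, negative
scale marker) with 0 encoding "no depth"; point clouds as ASCII or
binary-little-endian PLY. Images are PNG (no JPEG reader is linked; PNG is
lossless, which matters for masks and the byte-identity reproducibility
tests).

## Edge extraction and the 4-channel input

`canny_edges()` is the standard pipeline: Gaussian smoothing (σ = 1 px;
the literature the defaults come from does not state a smoothing width, so
it is exposed), Sobel gradients, L2 gradient magnitude (L1 available),
discrete non-maximum suppression over four quantized directions, and
double-threshold hysteresis with 8-connectivity. The default thresholds are
low = 50, high = 150 on 8-bit-range magnitudes — the balance between edge
preservation and noise suppression used for plant imagery. Color images are
reduced to luminance (0.299 R + 0.587 G + 0.114 B) first; running per
channel and OR-ing is a plausible alternative the package does not take.
`concat_edge_channel()` appends the mask as a fourth 8-bit channel
(255 = edge), leaving the RGB bytes untouched.

`depth_edge_mask()` min-max normalizes the valid depths to 8-bit before
Canny so that the 50/150 thresholds are scale-free across scenes; the
result is intersected with the validity mask so invalid regions can never
contribute edges.

## Losses

Depth is discretized into K hypotheses `d_k = d_min + k·Δd`,
`Δd = (d_max − d_min)/(K − 1)` (`depth_grid()`; the grids used in training
span 425–935 mm with K = 48/32/8 over three coarse-to-fine stages).
`nearest_hypothesis()` returns `argmin_k |d_k − d_true|` with ties broken
toward the smaller index and out-of-range depths clamped — both choices are
asserted against a brute-force scan.

**Focal loss.** With `P_i^{d̃}` the predicted probability at the hypothesis
nearest the true depth of valid pixel i,

$$L_{focal} = \frac{1}{N}\sum_{i=1}^{N} -(1-P_i^{\tilde d})^{\gamma}\,\log P_i^{\tilde d},\qquad \gamma = 2.$$

The natural logarithm is used (any base only rescales), probabilities are
floored at 1e-12 so degenerate volumes cannot produce −∞, and N counts
valid (plant) pixels only. γ = 0 recovers mean cross-entropy; a uniform
K = 8 volume at γ = 2 gives the closed-form per-pixel value
`(7/8)² · ln 8 ≈ 1.5921`, which the tests pin down.

**Edge-aware loss.** With `E` the Canny mask of the ground-truth *depth*
image and `G` a gradient-magnitude map,

$$L_{edge} = \frac{1}{M}\sum_{j=1}^{M} E_{gt,j}\,\lvert G_{gt,j}-G_{pre,j}\rvert .$$

M counts the masked pixels valid in both maps (reading "the corresponding
set of pixels in the edge mask" as the mask itself, not all valid pixels —
the normalization that makes the loss an *edge* average). The gradient
operator is central differences in the interior with one-sided fallbacks at
borders and beside invalid pixels, zero where no valid neighbour exists;
magnitude `√(gx² + gy²)`. Central differences are the minimal unbiased
choice; Sobel is available as a config alternative. The loss is invariant
to a shared constant offset of both maps (only gradients enter). An empty
mask yields 0 with a message — no edge supervision is available, not an
error.

**Total loss.** `L = Σ_s λ₁ˢ L_focal^s + λ₂ˢ L_edge^s` over 1–3 stages with
λ = (0.9, 0.1) for every stage by default; the per-stage breakdown is
returned so training code can log terms separately. All three losses are
asserted equal to unvectorized loop implementations to 1e-10.

## Fusion

`fuse_depth_maps()` follows the standard MVSNet-style recipe. Each view in
turn is the reference; its plant-masked valid pixels are lifted to 3D with
their depths and checked against the `num_source_views = 10` nearest
neighbouring views (by camera-centre distance — on a turntable ring this is
the adjacency ordering). A source confirms a pixel iff the
backproject → source-lookup → reproject round trip lands within
`max_reproj_px = 1` pixel of the start **and** the reference depth and the
source depth reprojected into the reference frame differ by less than
`max_rel_depth = 1%` relatively (both strict, as conventionally printed
"< 1", "< 1%"). Source lookups use nearest-pixel sampling so the sub-pixel
round-trip test is meaningful. A pixel that collects
`min_consistent_views = 4` confirmations emits one point whose depth is the
mean of the reference depth and all consistent reprojected source depths
(the reference participates once). Each reference pixel emits at most one
point; there is no cross-view deduplication beyond the gate. Setting
`min_consistent_views = 0` disables the gate — useful as the control arm
when measuring what the gate buys.

With point-splat-rendered depth maps, the 1 px round trip passes for
roughly 87% of co-visible pixels at 15° baselines; the residual is the
nearest-pixel rounding in the source view, an inherent property of the
mandated lookup. The 4-of-10 consensus still emits ~90% of plant pixels.

## Evaluation protocol

**Depth maps.** `mae_depth()` is the mean absolute error over pixels valid
in *both* maps (prediction holes are excluded and counted, not scored as
infinite); `epe_fraction()` is the share of pixels with error strictly
below n mm. `edge_annulus_mask()` builds the leaf-edge band: plant pixels
within 40 px (Euclidean distance transform, exact) of the mask complement,
with everything outside the image counted as complement. The annulus is
computed from the whole-plant silhouette; per-leaf silhouettes would need
instance labels the inputs do not carry. Cross-sample summaries use the
sample (n−1) standard deviation.

**Point clouds.** `evaluate_clouds()` computes `MAE_Distance_1` (mean
reconstructed-to-truth nearest-neighbour distance), `MAE_Distance_2` (the
reverse), their average, and the threshold metrics Acc, Comp (strict
< D_th, default 0.4 mm) and OP = (Acc + Comp)/2. Nearest-neighbour queries
run through an exact compiled kd-tree whose results are asserted identical
to exhaustive search. `icp_point_to_point()` alternates nearest-neighbour
correspondences with the closed-form SVD (Kabsch) update; the RMS sequence
is non-increasing and known rigid offsets (5°, 2 mm) are recovered to 1e-3
on noiseless clouds. Coarse alignment is an input (`init`), matching a
workflow where coarse registration is interactive.

**Leaf edges in 3D.** `segment_leaf_edges()` meshes the leaf cloud, finds
boundary edges (incident to exactly one face), and returns the input points
within 4 mm of a boundary vertex. Meshing
(`reconstruct_leaf_mesh()`) is a tangent-plane triangulation: PCA
projection to the principal plane, 2D Delaunay (compiled Bowyer–Watson),
then removal of triangles with any edge longer than 4× the cloud's
characteristic spacing. The spacing scale is the 95th-percentile
nearest-neighbour distance: for jittered-grid sampling it equals the grid
step, while for Poisson-random sampling the *median* NN distance is roughly
half the mean inter-point distance and would prune interior triangles
(about 40% area loss on a random-sampled disc in development tests) — the
higher quantile is robust to both. The filter is what removes the
convex-hull triangles spanning rim concavities, the over-extension this
pipeline must guard against. The method assumes an open surface that does
not fold over its principal plane — true of leaf patches, not of closed
objects; closed surfaces are outside its domain.

**Phenotypes.** `plant_height()` is the extent along the up axis (world +z
by default, any axis accepted); `leaf_area()` is the summed triangle area
of the filtered mesh; `agreement_stats()` computes
`R² = 1 − Σ(y−ŷ)²/Σ(y−ȳ)²` and `MAPE = (100/n)·Σ|y−ŷ|/y`, erroring on the
undefined cases (zero truth values, constant truth vector).

## Synthetic scenes

`make_scene()` exists so every claim above is testable without data
downloads. The plant is a vertical stem cylinder spanning exactly
`[0, plant_height]` plus paraboloid leaf lobes with sinusoidally rippled
rims — genuine depth discontinuities at leaf edges, the regime edge-aware
methods target. The default acquisition mirrors a turntable rig: 48 poses,
15° azimuth steps, two ring heights, all cameras fixating the plant
centroid.

Imaging defaults are chosen so the protocol's thresholds are meaningful:
512×512 px at 1250 px focal length and 500 mm stand-off gives a ~0.4 mm
pixel footprint at the plant — comparable to evaluating 864×1152 images of
a half-metre rig — which is the scale at which a 0.4 mm point-distance
threshold discriminates. The ground-truth cloud is sampled at 0.35 mm
(denser than the footprint, so z-buffer rendering with splat radius 0
covers every pixel; `render_depth()`'s default splat radius of 1 exists for
sparser scanner-grade clouds). Isolated pixels the jittered sampling missed
are closed by `fill_depth_pinholes()` (an invalid pixel with ≥ 6 valid
8-neighbours takes their mean; straight silhouette borders have at most ~5
valid neighbours and are untouched).

"Predicted" depth maps are ground truth plus seeded Gaussian noise
(`noise_sigma`), optionally with extra corruption within `edge_band_px` of
depth-Canny edges (`edge_noise_sigma`) to emulate the edge-concentrated
error structure of real MVS predictions. One RNG stream per artifact type
(cloud sampling vs noise), both derived from the master seed, so toggling
noise does not change the sampled plant; two runs of the same spec produce
byte-identical files.

For edge-region experiments the plant needs leaf interiors extending beyond
the 40 px annulus, otherwise the annulus *is* the plant and edge and
overall MAE coincide. Foreshortening makes this surprisingly demanding:
with 60 mm leaves nearly every plant pixel lies within 40 px of background.
The edge-behaviour fixtures therefore use three 140 mm leaves in an 896 px
frame (annulus covers ~85% of the plant, leaving a clean interior
control region).

What the generator does **not** emulate: photometric texture (RGB proxies
are depth-shaded), scanner occlusion artifacts beyond z-buffer visibility,
leaf thickness (surfaces are one-sided sheets), wind/registration error,
and the error structure of a real depth network beyond
Gaussian-plus-edge-corruption. Tests passing on these scenes validate the
geometry, metrics and fusion logic — not network accuracy on real plants.

## Numerical choices and degenerate inputs

- Quantization bound for closed-loop checks: a fused point is emitted along
  a pixel-centre ray with a depth taken from a sample up to half a pixel
  away, so distances to the generating surface are bounded by about one
  pixel footprint at the far side of the plant
  (`(ring_radius + 150)/focal ≈ 0.52 mm` at the defaults); the measured
  closed-loop MAE_Distance (~0.2 mm) sits well inside it. Closed-loop
  completeness is evaluated against the *visible* subset of the generating
  cloud (`visible_points()`): points occluded in every fused view are
  unreachable by any multi-view method.
- `nearest_hypothesis()` ties go to the smaller index; out-of-range depths
  clamp. Probability floors (1e-12) precede logs.
- The Euclidean distance transform is the exact two-pass lower-envelope
  algorithm; the annulus therefore matches a brute-force per-pixel scan
  *exactly*, which a test asserts.
- Delaunay input is normalized to a unit box; cocircular quadruples (grid
  data) resolve to either diagonal, both valid triangulations — area-based
  assertions are unaffected.
- ICP requires rank-3 cross-covariance and reports degeneracy (collinear
  clouds) as an error naming the cause; reflections are excluded by the
  sign correction in the SVD update.
- Empty evaluation sets (no co-valid pixels, empty clouds) are errors;
  an empty edge mask in the edge-aware loss is a 0 with a message; a
  single-view fusion is a warning plus an empty cloud, since consensus is
  impossible rather than wrong.

## Problem sizes

The test suite exercises unit fixtures at 96–192 px and the full protocol
at its native 512 px (closed loop, 48 poses with 12 reference views fused)
and 896 px (edge-corruption experiment, 12 poses, 4 reference views); the
acceptance script runs the same sizes. These are the sizes at which the
quantization analysis above holds; everything scales with the spec fields
if larger scenes are wanted.

## Known limitations

- The surface reconstructor handles open, non-folding patches only; it is a
  leaf-meshing tool, not a general closed-surface reconstructor.
- Depth-map fusion assumes reasonably accurate camera calibration; there is
  no bundle adjustment or pose refinement.
- The whole-plant annulus approximates per-leaf edge bands; touching leaves
  share one silhouette.
- JPEG inputs are not read; convert to PNG upstream.
- No lens distortion model (upstream structure-from-motion is expected to
  have undistorted the images).
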