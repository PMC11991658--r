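# leafmvs

Edge-aware multi-view stereo (MVS) reconstruction and evaluation for plant
phenotyping, in R.

Camera-based 3D reconstruction of plants is attractive because RGB cameras
are cheap, but leaf *edges* — thin, rippled, depth-discontinuous — are
exactly where MVS depth estimation fails worst, and edge errors propagate
into the point cloud and into downstream traits such as leaf area. This
package implements the computational core of an edge-aware MVS pipeline for
people who work on plant reconstruction methods:

- **Edge-augmented inputs** — Canny edge extraction (hysteresis thresholds
  50/150 by default) and concatenation into 4-channel (R, G, B, Edge)
  network inputs.
- **Training losses over discretized depth hypotheses** `d_k = d_min + k·Δd`:
  the focal loss
  `L_focal = (1/N) Σ_i −(1−P_i^{d̃})^γ · log P_i^{d̃}` (γ = 2), the
  edge-aware gradient loss
  `L_edge = (1/M) Σ_j E_gt,j · |G_gt,j − G_pre,j|`, and the staged total
  `L = Σ_s λ₁ˢ L_focal + λ₂ˢ L_edge` with λ = (0.9, 0.1) per stage.
- **Geometric-consistency depth-map fusion** — plant-mask filtering, the
  reproject-and-check gate (‖t_r − t_reproj‖ < 1 px and relative depth
  difference < 1%, 4 of 10 adjacent source views required), and geometric
  averaging of consistent depths into a point cloud.
- **The full evaluation protocol** — depth MAE, EPE_n (fraction of pixels
  with error < n mm), the 40-px leaf-edge annulus; point-cloud
  MAE_Distance/Acc/Comp/OP at D_th = 0.4 mm; point-to-point ICP; leaf-edge
  segmentation via surface meshing with a 4 mm boundary-distance threshold;
  leaf area and plant height with R²/MAPE agreement statistics.
- **A deterministic synthetic-scene generator** — a parametric plant
  (stem + paraboloid leaves with rippled rims) imaged by the standard
  48-pose two-height camera ring at 15° steps, with rendered ground-truth
  depth maps — so the whole pipeline runs end to end with no external data.
- **I/O for the MVS interchange formats**: MVSNet-style `cam.txt`, PFM depth
  maps, PLY point clouds (ASCII + binary), PNG images and masks.

The depth-inference network itself (feature pyramids, transformers, cost
volumes) is out of scope: depth maps are inputs here.

## Worked example

Simulate a plant, fabricate noisy "predicted" depth maps, fuse them under
the consistency gate, and evaluate:

```r
library(leafmvs)

spec <- scene_spec(n_views = 12, heights = 280, angular_step = 30,
                   seed = 7, noise_sigma = 1,
                   image_width = 256, image_height = 256,
                   focal_px = 625, point_spacing = 0.7)
sc <- make_scene(spec)

# depth-image evaluation of view 1 against its ground truth
evaluate_depth(sc$gt[[1]], sc$pred[[1]], edge_width_px = 40)
#> <depth_eval_report: MAE 0.7976 mm (edge 0.7976 mm), epe_2=0.954 epe_4=1.000,
#>  n=5204 (edge 5204, excluded 0)>

# fuse all 12 views: 4 of 10 sources must confirm each pixel
views <- lapply(seq_along(sc$views), function(i)
  list(depth = sc$pred[[i]], plant_mask = sc$masks[[i]]))
fused <- fuse_depth_maps(views, consistency_params(
  min_consistent_views = 4, num_source_views = 10))
fused
#> <point_cloud 19372 points>

evaluate_clouds(fused, sc$cloud, d_th = 2)
#> <cloud_eval_report: MAE 1.001 mm (rec->gt 0.4158, gt->rec 1.586);
#>  Acc 100.00% Comp 74.38% OP 87.19% @ 2 mm>

plant_height(fused)   # mm; the generating plant is 120 mm tall
#> [1] 120.8875
```

The per-view MAE of ~0.80 mm is the half-normal mean `σ·√(2/π)` of the 1 mm
injected noise; fusion averages ≥ 5 depth estimates per point, which is why
the fused cloud's accuracy error (0.42 mm) is well below the per-view noise.
Completeness is below 100% because parts of the plant (inner stem,
under-leaf) are occluded in every view.

A thin command-line front end over the same functions lives at
`inst/cli/leafmvs.R`:

```sh
Rscript inst/cli/leafmvs.R simulate --spec spec.yaml --out scene/
Rscript inst/cli/leafmvs.R fuse --scene scene/ --min-views 4 --num-src 10 --out cloud.ply
Rscript inst/cli/leafmvs.R eval-cloud --rec cloud.ply --gt scene/cloud.ply --dth 0.4 --json report.json
```

## Documentation

The methods vignette (`vignettes/edge-aware-plant-mvs.Rmd`) describes the
model and the evaluation protocol, every tunable parameter with its unit
and default, what the synthetic scenes do and do not emulate, and the
numerical choices (gradient operators, tie-breaking, quantization bounds,
degenerate inputs).
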