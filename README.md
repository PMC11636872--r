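# bgsal — background-prior salient object detection

`bgsal` detects the visually salient object in an RGB image without any
trained model, using only the *background prior*: regions near the image
border are usually background, so every region can be scored by how badly a
dictionary of boundary regions reconstructs it. The approach targets the
classic failure mode of that prior — a salient object that touches the image
border and thereby poisons the dictionary — by refining the dictionary with
a boundary-conductivity measure before any reconstruction happens. Typical
users are computer-vision researchers who need a transparent, CPU-only,
training-free baseline (e.g. for assistive-vision pipelines or as a mask
initializer for heavier segmentation refiners).

## The model

1. **Abstraction.** The image is decomposed into SLIC superpixels at several
   scales (default 50–400 segments). Each superpixel `i` carries the feature
   vector `f_i = [R, G, B, L, a, b, x, y]` (mean colors; centroid normalized
   to [0, 1]).
2. **Dictionary refinement.** On the superpixel adjacency graph with
   appearance edge weights, the geodesic distance `d_geo` defines a soft
   area `Area(p) = Σ_i exp(−d_geo(p, p_i)² / 2σ²)` and a soft border length
   `Length(p)` (the same sum restricted to boundary superpixels). The
   *boundary conductivity* `BC(p) = Length(p) / √Area(p)` is scale invariant
   (on a homogeneous image it equals `k′/√k` at every patch scale); boundary
   superpixels with `BC` below the adaptive threshold
   `τ = BC_max − K·var(B)` (K = 4) are deemed object parts and dropped,
   yielding the refined dictionary `B*`.
3. **Reconstruction errors.** Each superpixel is scored twice against `B*`:
   the **dense** error is the squared residual after projection onto the PCA
   basis of `B*` (`γ_i = Vᵀ(f_i − f̄)`, `ε_i^D = ‖f_i − (Vγ_i + f̄)‖²`), and
   the **sparse** error is the residual of the L1-regularized code
   `α_i = argmin ‖f_i − B*α‖² + λ‖α‖₁` (λ = 0.01). Background regions
   reconstruct cheaply; salient ones do not.
4. **Propagation and fusion.** Errors are smoothed inside K-means appearance
   clusters, lifted to pixels by similarity-weighted averaging across
   scales, re-weighted by a Gaussian centered on the error-weighted
   centroid, and the dense and sparse maps are fused by Bayesian
   integration (each map serves as the prior for the other).
5. **Mask.** Otsu thresholding, removal of components under 10% of the
   largest, hole filling — plus a pluggable hook for any external mask
   refiner.

The package also ships the full evaluation suite used in the saliency
literature (MAE, PR curves, F1/Fβ with β² = 0.3, ROC/AUC, S-measure,
E-measure, IOU, dataset aggregation) and a seeded synthetic-scene generator
(`make_suite()`) covering the regimes benchmarks probe: centered objects,
multiple objects, low contrast, cluttered backgrounds, and near-boundary
objects — so the whole pipeline is testable without downloading a dataset.

## Worked example

```r
library(bgsal)
suite <- make_suite(42)           # 20 seeded scenes with ground truth
scene <- suite[[1]]               # a centered high-contrast ellipse
res   <- detect(scene$image, sod_config())
iou(res$initial_mask, scene$gt)
r <- evaluate_pair(res$saliency, scene$gt, mask = res$initial_mask)
aggregate_dataset(list(r))
```

prints

```
IOU(initial mask, ground truth) = 1.000
eval_report over 1 image(s)
  MAE 0.0002 | F1 1.0000 | Fb 1.0000 | AUC 1.0000 | S 0.9999 | E 1.0000 | IOU 1.0000
  IOU > 0.90: 100.0% | MAE < 0.10: 100.0%
```

i.e. on this synthetic scene the thresholded mask matches the ground truth
exactly and the saliency map separates object from background almost
perfectly (MAE is the mean per-pixel deviation of the graded map). Across
the full 20-scene suite the default configuration reaches a mean initial-mask
IOU of about 0.98 (see `tests/testthat/test-acceptance.R`, which also
verifies that disabling dictionary refinement collapses near-boundary
scenes to a mean IOU of ~0.14).

## Command line

```sh
inst/cli/bgsal synth  --out scenes --seed 1
inst/cli/bgsal detect --input scenes/images/centered_1.ppm --out out [--config cfg.json] [--save-intermediate]
inst/cli/bgsal eval   --pred out --gt scenes/gt --report report.json [--csv per_image.csv]
```

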