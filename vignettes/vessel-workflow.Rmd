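---
title: "Vessel enhancement, segmentation and branch labeling for TOF angiography: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel enhancement, segmentation and branch labeling for TOF angiography: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`vesseltrace` reconstructs and labels vascular trees in whole-body
time-of-flight (TOF) magnitude MR angiography of small animals. In 2D
multi-slice FLASH-TOF, inflowing blood enters each imaging slice
unsaturated and appears bright against the RF-saturated static tissue, so
vessels can be imaged without contrast agent. The price is strong voxel
anisotropy (here 0.117 × 0.117 mm in-plane versus 0.5 mm slices),
slice-to-slice intensity modulation from crosstalk between overlapping,
sequentially excited slices, and extreme class imbalance: vessels occupy
on the order of 1% of the body volume. The pipeline is deliberately
rule-based and deterministic — every stage is reproducible from a config
and a seed — and is validated end-to-end on synthetic phantoms with known
ground truth.

## The workflow

Five stages run in a fixed order (`run_pipeline()`):

1. **Body masking** (`compute_body_mask`). Otsu's threshold on the raw
   magnitude volume, morphological closing with a ball (radius 2 voxels),
   3D hole filling, then the largest 26-connected component. Parameter-free
   apart from the closing radius.
2. **Intensity conditioning** (`normalize_within_mask`,
   `gaussian_denoise`, `per_slice_normalize`). Within-body intensities are
   rescaled so the 1st/99th percentiles map to [0, 1] (robust to the few
   inflow-bright voxels), denoised with a 3D Gaussian of physical sigma
   0.12 mm (about one in-plane voxel — enough to suppress noise without
   erasing one-voxel vessels), and then each axial slice is divided by its
   within-body median and re-scaled by the global within-body median.
   The median is used because vessels are sparse within any slice; slices
   with fewer than 50 body voxels are left untouched because their median
   is too noisy to trust. The order (mask → normalize → denoise →
   per-slice) is fixed; normalizing before denoising keeps the slice
   statistic consistent with what the enhancement stage sees.
3. **Vesselness enhancement and fusion** (`vesselness`,
   `orthogonal_support_maps`, `fuse_maps`). Multiscale Hessian filtering
   for bright tubes: at each scale $\sigma$ the volume is smoothed with a
   Gaussian of per-axis sigma $\sigma/\mathrm{spacing}$ and
   second derivatives are taken by central differences in physical units
   (together one discrete Gaussian-derivative kernel — numerically well
   behaved even when $\sigma$ is a fraction of a voxel along the 0.5 mm
   slice axis). With eigenvalues ordered
   $|\lambda_1|\le|\lambda_2|\le|\lambda_3|$ and
   $R_A = |\lambda_2|/|\lambda_3|$,
   $R_B = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$,
   $S = \sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}$ ($\sigma^2$-normalized),
   the response is
   $(1-e^{-R_A^2/2\alpha^2})\,e^{-R_B^2/2\beta^2}\,(1-e^{-S^2/2c^2})$,
   zero wherever $\lambda_2>0$ or $\lambda_3>0$ (dark structures). Scales
   default to {0.12, 0.24, 0.36} mm — vessels of roughly 1–3 in-plane
   voxel radius; $\alpha=\beta=0.5$; $c$ defaults to half the maximum $S$
   within the body at that scale. Responses within $2\sigma_{\max}$ of the
   body boundary are zeroed: inside that margin the Hessian is dominated
   by the body/air edge and sheds spurious tube-like responses along the
   whole body outline. Orthogonal-plane support maps — sliding means of
   the vesselness over 5 consecutive slices perpendicular to each axis —
   reward structures that persist across slices; the final probability
   volume is the convex combination with weights (0.5, 1/6, 1/6, 1/6).
4. **Segmentation and skeletonization** (`hybrid_threshold_segment`,
   `remove_small_components`, `skeletonize_volume`). The threshold
   combines a percentile constraint with an Otsu-derived value: the 95th
   percentile of within-body probabilities bounds the candidate pool
   (vessels are well under 5% of the body), and Otsu's criterion applied
   to the *logarithm* of the candidate values separates vessels from the
   residual background tail. Otsu on the raw, extremely skewed
   distribution places its split inside the bright class itself;
   multiscale responses spread multiplicatively across vessel radii and
   contrast, so their classes are far closer to Otsu's symmetric-class
   assumption in the log domain. The final threshold is the larger of the
   two, so the foreground fraction can never exceed 5% (plus one-bin
   slack). Components under 27 voxels (a 3×3×3 speck) are removed, and
   the mask is thinned to a curve skeleton by sequential 6-subiteration
   deletion of simple points (26-connected foreground / 6-connected
   background, curve endpoints preserved) — topology-preserving and
   idempotent.
5. **Branch-level labeling** (`skeleton_to_graph`, `identify_trunk`,
   `propagate_branch_levels`, `colorize_labels`). The skeleton becomes a
   voxel graph (nodes = skeleton voxels, edges = 26-adjacent pairs
   weighted by physical distance). Per connected component the trunk is
   the maximum-physical-length simple path: the exact diameter of the
   component's minimum spanning tree, by two farthest-node sweeps. Levels
   then follow branch order: remove the trunk; each hanging part
   contributes its principal path (attachment to farthest voxel) as a
   level-1 branch; parts hanging off level-1 branches contribute level-2
   paths, and so on until the component is exhausted. Every voxel is
   labeled exactly once, and a level-k branch always emerges from a
   level-(k−1) branch — the semantics of the rendering taxonomy (trunk
   red, first-order green, second-order blue, higher orders magenta,
   tumor overlay purple beneath the vessels). All tie-breaks —
   MST edge order, farthest-node choices, path endpoints — are
   lexicographic on (z, y, x), so identical inputs give byte-identical
   label volumes.

```{r}
library(vesseltrace)
ph <- make_phantom_bundle(seed = 42, preset = "default")
res <- run_pipeline(ph$volume, outdir = "run", config = pipeline_config())
evaluate_against_truth(res$vessel_mask, res$labels, ph, tolerance_mm = 1.0)
```

## The phantom generator

No animal data ships with the package; every stage is validated on
seeded synthetic phantoms (`make_phantom_bundle`). The generator emulates
the acquisition the pipeline targets:

- **Grid**: the `default` preset uses 128 × 128 × 96 voxels at
  (0.117, 0.117, 0.5) mm — the emulated FLASH-TOF geometry (30 mm field
  of view over a 256 matrix gives 0.117 mm in plane; a 0.3 mm interslice
  distance under 0.5 mm slices is a 40% slice overlap, represented in
  the grid metadata rather than by explicit slice-profile convolution,
  since the pipeline consumes reconstructed grids). The `small` preset
  (64³ isotropic at 0.25 mm, depth-2 tree) keeps the test-suite fast.
- **Vessel tree** (`sample_vessel_tree`): recursive bifurcation with an
  asymmetric child pair — a continuation child (small tilt, radius ratio
  0.85, length ratio 0.8) and a side child (≈50° tilt, radius ratio 0.71,
  length ratio 0.3). The radius pair satisfies Murray's law
  (0.85³ + 0.71³ ≈ 1); a symmetric split (both ratios 2^(−1/3)) is the
  balanced special case. The asymmetry is deliberate twice over: real
  small-animal vasculature is side-branching (a dominant aorta-like
  trunk), and a symmetric binary tree has no identifiable main trunk at
  all — its longest path bypasses the root. The side length ratio 0.3
  keeps every side chain shorter than the trunk it leaves
  (0.3·(1+0.8+0.8²+0.8³) ≈ 0.89 < 1), so the ground-truth trunk is
  geometrically unambiguous with ≈11% margin over the 8% length noise.
- **Voxelization** (`voxelize_tree`): vessels are capsules (cylinders
  with hemispherical caps); the centreline marks voxels nearest each
  axis; ground-truth branch levels are derived from the segment tree with
  the trunk defined exactly as the pipeline defines it — the
  maximum-length path through the tree — so truth and prediction share
  one trunk semantics. Segments thinner than half the largest voxel
  dimension cannot be resolved and are rendered as their centreline,
  with a warning.
- **Intensity model** (`simulate_tof_volume`): body ellipsoid at level
  0.3, vessels at 0.9 (TOF inflow contrast must be positive), a tanh
  partial-volume ramp of one in-plane voxel at the vessel boundary,
  per-slice multiplicative drift — a smooth bounded random walk in
  [1−a, 1+a], a = 0.2 by default, emulating the slice-order-correlated
  crosstalk/saturation of sequential multi-slice excitation (correlated,
  not periodic, hence a random walk rather than a modulation) — and
  additive noise (Gaussian sd 0.05 by default; Rician available, since
  magnitude-MR noise is Rician, but the Gaussian default keeps analytic
  checks transparent). The tumor is a mask-only ellipsoid beside a
  mid-tree segment: the pipeline never uses tumor intensity, masks are
  carried for overlay rendering only.

What the phantom does *not* emulate: B1/bias fields, motion and flow
pulsation artifacts, respiratory displacement between slices, vessel
curvature within segments (segments are straight), anatomical surround
(organs of differing intensity), and partial-volume behaviour of the true
slice excitation profile. Passing the recovery gates on phantoms
therefore demonstrates the internal consistency and robustness of the
chain under controlled imaging physics, not segmentation accuracy on
animals; on real data the labels remain a qualitative QA aid.

## Numerical choices and degenerate inputs

- Connectivity is 26 for foreground everywhere (components, skeleton,
  graphs, propagation); background uses 6-connectivity (hole filling,
  thinning) — the complementary pair that keeps thinning
  topology-correct.
- Otsu histograms use 256 equal-width bins over the value range; the
  returned threshold is a bin edge, ties broken toward the lowest edge.
- Distances are Euclidean in physical units throughout (a Felzenszwalb
  squared-distance transform with per-axis spacing); centreline matching
  tolerance defaults to twice the largest voxel dimension (1.0 mm at the
  emulated geometry) to absorb one-voxel skeleton jitter; nearest-truth
  ties break lexicographically on (z, y, x).
- Constant volumes are rejected by the body-mask and normalization
  stages (degenerate-input errors naming the condition); a constant
  probability map segments to an empty mask with a warning; an empty
  skeleton yields an empty graph and no labels.
- Gaussian smoothing uses replicate-edge boundaries and kernels cut at
  4σ, renormalized to unit mass so constants are preserved exactly.
- The manifest written by `run_pipeline()` echoes the fully materialized
  config, the thresholds actually used, and per-stage voxel counts, and
  contains no wall-clock information — timing lives in the run log — so
  identical runs produce byte-identical manifests and label volumes.

## Problem sizes used in validation

The test-suite validates operations on small analytic fixtures (tubes,
plates, Y-skeletons, random voxel trees of ≤ 200 nodes), property checks
over 20 seeded `small` phantoms (64³), and one full end-to-end run at the
`default` 128 × 128 × 96 preset with seed 42, where the recovery gates
(Dice ≥ 0.6, centreline recall ≥ 0.8 and precision ≥ 0.7 at 1 mm, trunk
overlap ≥ 0.8, branch-level accuracy ≥ 0.8) are asserted. These sizes
were chosen so the whole suite runs in well under a minute while the
end-to-end case still exercises the anisotropic acquisition geometry at
full scale.

## Known limitations

- The trunk is defined purely geometrically (longest path). When the
  thresholded mask merges two branches near a junction, the skeleton
  graph acquires a shortcut and the predicted diameter path can divert
  from the anatomical trunk; across random phantom seeds the trunk
  overlap consequently varies while Dice and centreline recall stay
  high. A probability-weighted path criterion could reduce this but
  would couple the trunk definition to the enhancement stage.
- Branch levels are a heuristic visualization taxonomy, not an
  anatomical classification.
- Tumor masks are resampled by header affine (nearest neighbour) only;
  no image-to-image registration is attempted.
- The percentile constraint assumes vessels are under 5% of the body
  volume; denser vasculature (or tighter body crops) would need the
  percentile lowered in the config.
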