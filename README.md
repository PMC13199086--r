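# vesseltrace

Whole-body vessel analysis for time-of-flight (TOF) MR angiography of
small animals, as a tested, deterministic R pipeline. In 2D multi-slice
FLASH-TOF, inflowing blood is bright against saturated tissue, so the
vascular tree can be imaged without contrast agent — but the volumes are
strongly anisotropic (0.117 × 0.117 mm in-plane, 0.5 mm slices), carry
slice-to-slice intensity drift from crosstalk between overlapping
slices, and vessels occupy roughly 1% of the body: extreme class
imbalance. `vesseltrace` turns such a magnitude volume into a vessel
mask, a centreline skeleton and a hierarchical branch-level labeling,
and ships a synthetic phantom generator with full ground truth so every
stage is verifiable without animal data.

The pipeline (`run_pipeline()`):

1. **Body mask** — Otsu threshold, morphological closing, 3D hole fill,
   largest 26-connected component.
2. **Intensity conditioning** — robust percentile rescaling to [0, 1]
   within the body, 3D Gaussian denoising (σ = 0.12 mm), and per-slice
   median normalization within the body mask (recovers crosstalk drift).
3. **Vesselness + fusion** — multiscale Hessian tube enhancement for
   bright vessels: with $|\lambda_1|\le|\lambda_2|\le|\lambda_3|$,
   $R_A=|\lambda_2|/|\lambda_3|$, $R_B=|\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$,
   $S=\|\lambda\|_2$, the per-scale response is
   $(1-e^{-R_A^2/2\alpha^2})\,e^{-R_B^2/2\beta^2}\,(1-e^{-S^2/2c^2})$,
   maximized over scales {0.12, 0.24, 0.36} mm, then fused with
   orthogonal-plane support maps (5-slice sliding means) by convex
   weights (0.5, 1/6, 1/6, 1/6).
4. **Segmentation + skeleton** — hybrid threshold (95th-percentile
   candidate constraint + log-domain Otsu within the candidates),
   small-component removal, topology-preserving 3D thinning.
5. **Branch labeling** — skeleton graph with physical edge lengths;
   trunk = maximum-length path (MST diameter, deterministic
   lexicographic tie-breaks); recursive branch-order levels (trunk red,
   first-order green, second-order blue, higher magenta, tumor purple)
   and MIP QA renders.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
synthetic phantom; each can also be run line by line:

```sh
Rscript analysis/01_simulate_phantom.R   # phantom + ground truth
Rscript analysis/02_run_pipeline.R       # the five-stage workflow
Rscript analysis/03_evaluate_recovery.R  # metrics vs ground truth
Rscript analysis/04_group_summary.R      # cohort CSV descriptives
```

which prints, for the default 128 × 128 × 96 phantom (seed 42):

```
phantom written to results/phantom
  grid 128 x 128 x 96 at 0.117 x 0.117 x 0.5 mm
  emulated in-plane resolution 0.1172 mm, slice overlap 40%
  tree: 31 segments; vessel voxels 3481 (0.65% of body)
  slice drift range [0.800, 1.200], noise sigma 0.050

pipeline complete; outputs in results/run
  body 532702 voxels; vessel 2638; skeleton 152 in 1 component(s)
  threshold used 0.0424 (Otsu-derived 0.0424, p95 constraint 0.0097)
  levels: trunk 72 | first-order 67 | second 13 | higher 0

phantom recovery vs ground truth (tolerance 1 mm):
  Dice                 0.837
  centreline precision 1.000, recall 0.933
  trunk overlap        0.983
  branch-level accuracy 0.888 over 152 matched voxels
```

Reading the numbers: the vessel mask overlaps the true capsules with
Dice 0.84; every predicted skeleton voxel lies within 1 mm of a true
centreline (precision 1.0) and 93% of the true centreline is recovered;
98% of the true trunk is covered by the predicted trunk, and 89% of
matched skeleton voxels receive the correct branch level. The run
directory also holds the fused probability map, the branch-label volume
(NIfTI int16), a per-component CSV, color MIP renders, and a
deterministic `run_manifest.json` echoing every parameter and threshold
actually used (two identical runs are byte-identical).

For real data: `run_pipeline("volume.nii.gz", outdir, config)` accepts
any 3D NIfTI magnitude volume; an optional tumor mask (NIfTI, any grid)
is resampled by header affine for the overlay renders. Parameters live
in a strict YAML config (`read_pipeline_config()`), unknown keys
rejected.

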