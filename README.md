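# pscdiff

Image-based machine-learning control of pluripotent stem cell (PSC)
differentiation from whole-well bright-field microscopy.

Directed differentiation — PSCs to cardiomyocytes, nephron progenitors or
definitive endoderm — is highly sensitive to the CHIR99021 dose
(concentration in μM and duration in h) applied in stage I and to the state
of the starting colonies, and fails silently until fluorescent fate markers
appear days later. `pscdiff` implements a label-free monitoring and control
toolkit around bright-field images:

- **Efficiency quantification** from fluorescence labels: the
  Differentiation Efficiency Index
  `(1/W²) Σ_{I_ij > α} I_ij` with α = 0.5, plus per-line normalization.
- **Early CHIR-dose assessment** from 0–12 h image streams: a 21-D
  handcrafted representation (differential box-counting fractal dimension,
  local-entropy colony statistics, dense optical flow, pooled over
  pre/mid/post phases), a regularized multinomial logistic dose classifier,
  ANOVA feature selection, and the Deviation Score
  `(N_c^high − N_c^low)/N_c ∈ [−1, 1]` per concentration with
  leave-one-batch-out validation.
- **Initial colony-state control**: a 343-D morphological profile of 0 h
  colonies (texture, Hu moments, bag-of-keypoints histograms, shape and
  centroid–contour-distance statistics, spacing) with random-forest feature
  importance (1000 trees, depth 8) and efficiency prediction (20 trees).
- **Weakly supervised region localization**: patch-level labels from
  three-level masks (positive ≥ 30% dark gray; negative only-black), a
  pluggable CNN patch classifier, gradient-weighted class-activation maps
  `ReLU(Σ_k α_k A^k)` with `α_k = (1/Z) Σ_ij ∂y₊/∂A^k_ij`, whole-well
  reconstruction, the six standard segmentation metrics, and
  compound-screen ranking (top-40, ≥ 40% candidate rule).
- **Bright-field → fluorescence translation**: a scaled-down conditional
  adversarial translator (U-Net generator with instance normalization and
  nearest-neighbor upsampling; patch discriminator with a verified 16 × 16
  receptive field; objective `λ·L1 + cGAN`, λ = 100, adversarial term
  disabled for the second half of training) with pixel-level Pearson
  evaluation.
- **A synthetic well generator** that emulates the study conditions —
  multi-colony wells with textured interiors, a unimodal dose response in
  log concentration with line-specific optima, dose-proportional colony
  contraction over 0–12 h — so every component is testable without any
  external data.

Data containers are Bioconductor-style S4 classes (`WellImage`,
`ImageStream`, `RegionMask`, `SyntheticPlan`); imaging is built on EBImage,
models on glmnet and ranger, and the hot numeric kernels (sliding local
entropy, differential box counting, block-matching flow, im2col) are C++.

## Worked example

Generate a small synthetic batch spanning 2–10 μM CHIR around a 6 μM line
optimum, label the doses, and extract stream features for one well:

```r
library(pscdiff)

plan  <- syntheticPlan(nWells = 10L, seed = 42L)
batch <- generateBatch(plan)
labelDoses(batch$records, duration = 24)
#> DoseLabeling (24 h): optimal range [6, 6] uM
#>  chir_um   mean_value   class delta_chir
#>        2 1.905197e-05     low         -4
#>        4 7.729597e-02     low         -2
#>        6 2.442548e-01 optimal          0
#>        8 1.496469e-01    high          2
#>       10 3.208564e-02    high          4
```

The mean positive fraction per concentration is unimodal with a peak at the
optimum; only 6 μM clears the 20% rule, so the optimal range is [6, 6] and
the other concentrations are classed low/high with their signed ΔCHIR
distance in μM.

```r
eff <- efficiencyIndex(batch$store("B1_W003", "well")$fluor)
eff
#> Efficiency Index 0.1964 (positive fraction 0.2381 at alpha = 0.50)

fv <- streamFeatureVector(batch$store("B1_W003", "stream"))
round(fv[c("Area.pre", "Area.post", "CellBrightness.pre",
           "CellBrightness.post", "FractalDimension.pre")], 3)
#>            Area.pre           Area.post  CellBrightness.pre
#>               0.905               0.762               0.530
#> CellBrightness.post FractalDimension.pre
#>               0.549               2.337
```

This optimal-dose well scores an efficiency index of 0.196 (24% of pixels
above threshold). Its stream shows the early compaction response the dose
model reads: normalized colony area falls from 0.905 (pre-phase) to 0.762
(post-phase) while colony brightness rises — both at a rate that grows with
dose — and the fractal dimension of the bright-field surface sits mid-band
near 2.34. Training `trainDoseClassifier()` on these 21-D vectors labels
new wells low/optimal/high within the first 12 h, and
`deviationScores()` turns the per-well predictions into a per-concentration
dose-deviation readout.

A command-line front end is available at `inst/cli/psc.R`:

```sh
Rscript inst/cli/psc.R io-plan --wells 96 --grid 5 --z 3
# 7200 tiles (96 wells x 5 x 5 grid x 3 z)
```

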