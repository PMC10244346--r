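---
title: "Label-free control of PSC differentiation: models and methods"
author: "pscdiff maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free control of PSC differentiation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Directed differentiation of pluripotent stem cells (PSCs) — to
cardiomyocytes (CMs) via cardiac progenitor cells (CPCs), to nephron
progenitors, or to definitive endoderm (DE) — is notoriously variable
between batches, lines and wells.  Two of the strongest levers are the
concentration (μM) and duration (h) of CHIR99021, the GSK3-inhibiting Wnt
activator applied in stage I, and the state of the PSC colonies at the
moment induction starts.  Both act long before any fate marker is
expressed, so by the time immunofluorescence (cTnT for CMs, SIX2 for
nephron progenitors, SOX17 for DE) reveals a failed batch the cells and
weeks of work are gone.

`pscdiff` implements a purely image-based control strategy around this
problem: bright-field microscopy, which is label-free and non-invasive, is
mined for quantitative signatures that (i) score a finished well, (ii)
assess the CHIR dose within the first 12 h, (iii) predict final efficiency
from the 0 h colony state, (iv) localize committed progenitor regions at
intermediate stages without pixel-level supervision, and (v) translate
bright-field images directly into predicted fluorescence.

# Data model

Four S4 containers carry the data: `WellImage` (one grayscale whole-well
image, intensities on the internal [0,1] scale), `ImageStream` (exactly ten
frames T1–T10 uniformly spaced over 0–12 h plus dose metadata),
`RegionMask` (pixel fate labels over the fixed 8-bit palette black = 0,
light gray = 128, dark gray = 192, white = 255) and `SyntheticPlan` (the
design of a simulated batch).  Intensities live in [0,1] everywhere inside
the package; 8-/16-bit integer scales appear only in file I/O (16-bit TIFF
for images, 8-bit PNG for masks) and in the 0–255 normalization step of
class-activation maps.  Patch tiling uses 0-based origins with half-open
extents and re-anchors the last patch of each axis flush to the image edge,
so coverage is complete without synthetic padding that would distort
texture statistics.

# Scoring a well: the Differentiation Efficiency Index

For a fluorescence image $I$ with $W^2$ pixels the index is

$$\mathrm{Index} = \frac{1}{W^2} \sum_{I_{ij} > \alpha} I_{ij}, \qquad \alpha = 0.5 ,$$

the mean of above-threshold intensities over all pixels
(`efficiencyIndex()`).  The companion `positive_fraction` — the fraction of
pixels above $\alpha$ — is the package's image-based proxy for "percentage
of marker-positive cells"; how that percentage was originally measured
(image area versus cytometry) is not specified by the protocols this
package follows, so the proxy is explicit and configurable rather than
hidden.  Because differentiation potential differs between lines even at
optimal dose, `normalizeEfficiencies()` rescales every well by the maximum
of its cell line.

# Early dose assessment from 0–12 h image streams

Within hours of CHIR addition, colonies contract, densify and brighten at a
rate that depends on dose.  `streamFeatureVector()` turns a ten-frame
stream into 21 numbers: six *Type-I* features per frame — differential
box-counting fractal dimension; mean local entropy of cell regions; Area,
Circumference and their ratio; cell brightness — and one *Type-II* feature
per consecutive frame pair, the dense optical-flow magnitude.  Area,
Circumference, A–C ratio and Optical Flow are normalized by the first value
of their sequence (a first value below $10^{-6}$ leaves the sequence
unnormalized and flagged), frames are pooled into pre/mid/post phases, and
the $7 \times 3$ phase means form the feature vector.

Choices the protocol leaves open, fixed here:

* **Phase split.** Type-I frames pre = T1–T3, mid = T4–T7, post = T8–T10;
  Type-II pairs pre = (1–3), mid = (4–6), post = (7–9).  Contiguous,
  near-equal thirds; configurable via `phasesI`/`phasesII`.
* **Cell regions** are pixels whose disc neighborhood (Euclidean radius 10)
  has Shannon entropy ≥ 3 bits over the 256-bin 8-bit histogram.  The
  colony-state module uses radius 5, as each protocol states; both radii
  are kept as parameters.
* **Differential box counting** uses box widths $2, 2k, \dots, 2k^{15}$
  with $k = 243^{1/15}$ (so the largest box is 486 px), the grid anchored
  at the origin, partial edge cells included, 256 gray levels, box height
  $h = r\,G/M$, and a least-squares fit of $\log N(r)$ on $\log r$ over all
  16 widths.  The result is clipped to the theoretical band [2,3] with a
  warning; a constant image comes out at the planar dimension 2, seeded
  uniform noise near 2.83.  Images must be at least 486 px on a side.
* **Optical flow** is estimated by coarse-to-fine block matching: 16-px
  windows, SSD search with parabolic sub-pixel refinement, and a match
  accepted only when its SSD is below a quarter of the zero-displacement
  SSD (this rejects windows whose content left the frame).  Vectors with
  magnitude ≤ 4 px are discarded and the mean magnitude of the survivors is
  the feature.  On planted rigid shifts of 5–16 px the estimate is within a
  few percent.  A dedicated dense-flow library is not available in this
  stack; block matching satisfies the same contract and is validated by the
  planted-shift tests.

Doses are labeled per batch and duration by `labelDoses()`: concentrations
whose mean positive fraction reaches 20% form the optimal range
$[c_1, c_2]$; others are low/high with the signed distance
$\Delta\mathrm{CHIR}$ ($c - c_1$ below, 0 inside, $c - c_2$ above).  The
classifier (`trainDoseClassifier()`) is a multinomial logistic model
(glmnet) with inverse-class-frequency weights and preset regularization:
l1 with coefficient 1/4 at 24 h and 1/8 at 36/48 h on all 21 features, l2
with 0.1 on the four ANOVA-selected features, and elastic net (l1-ratio
0.1, weight 0.05) for cross-batch validation; the preset strength enters
glmnet as a per-observation penalty (`lambda = strength / n`).  One-way
ANOVA F statistics across the three classes drive feature selection
(`selectFeaturesAnova()`, ties to the lower index).  Predictions aggregate
into the Deviation Score per concentration,

$$\mathrm{Deviation\ Score}(c) = \frac{N_c^{\mathrm{high}} - N_c^{\mathrm{low}}}{N_c} \in [-1, 1],$$

with the per-concentration count $N_c$ in the denominator — the only
reading consistent with the printed [−1,1] range.  `crossBatchValidate()`
runs the leave-one-batch-out loop with per-round feature selection, and
`chooseDuration()` picks the duration whose score is closest to zero (ties
to the shorter duration).

# The 0 h colony state

`colonyFeatureVector()` quantifies an initial-colony image with 343 named
features: {LocalEntropy, CellBrightness, CellContrast, TotalVariation},
Hu moments 1–7, a 256-bin and a 64-bin bag-of-keypoints histogram, {Area,
Circumference, ACRatio}, {Solidity, Convexity, Circularity}, five
centroid–contour-distance (CCD) statistics, and Spacing.  Shape statistics
are computed per 8-connected component and averaged with area weights;
components under 50 px are dropped as specks (configurable).  Perimeters
are polygonal arc lengths of the outer contour resampled at ~5 px — this
stabilizes Convexity and Circularity near 1 for smooth shapes, where raw
chain-code lengths overcount by several percent — and Circularity pairs
that perimeter with the contour polygon's area so that a digitized disc
scores 1.  Convex-hull areas get a lattice-point (Pick-type) correction so
a convex component has Solidity exactly 1.  Spacing skeletonizes the
cell-free complement (Zhang–Suen thinning) and averages, over skeleton
pixels, the distance to the nearest cell pixel.  Hu moments are computed on
the raw grayscale image without the log-magnitude transform (the protocol
is silent; raw values are kept and documented).

Random forests (`fitForest()`, via ranger) come in two modes exactly as
published: feature importance with 1000 trees of depth 8 and 15 candidate
features per split (importances normalized to sum to 1), and efficiency
prediction with 20 trees.  `predictEfficiency()` clips predictions to
[0,1].

# Keypoint features and trajectory projections

`descriptorSummary()` summarizes an image by the per-dimension mean and
population standard deviation of three keypoint-descriptor families of 128,
64 and 32 dimensions — a $(128+64+32)\times 2 = 448$-D vector.  Keypoints
are Harris corners with a dominant gradient orientation; the 128-D family
is a 4×4×8 gradient-orientation histogram, the 32-D family packs 256 fixed
binary intensity tests into bytes, and the 64-D slot is a 4×4 grid of
signed/absolute gradient sums in the classical 64-D layout.  The classical
64-D descriptor itself is patent-encumbered and absent from this stack, so
the slot is pluggable and the substitution is recorded in the result
metadata — the 448-D layout is stable either way.  Detector parameters are
library defaults in one config block and reported per run; they are not
presumed to match any external implementation's.

Bag-of-keypoints codebooks (`fitCodebook()`) are k-means (k = 256 for the
128-D family, k = 64 for the 32-D family) over keypoints pooled from a
fitting image set whose ids are stored so downstream train/test sets stay
disjoint.  `projectLDA()` implements shrinkage LDA — the within-class
scatter shrunk toward a scaled identity, as used with shrinkage 0.1 for
21-D features and 0 for 4-D — because no installed package provides
shrinkage LDA; `projectPCA()` wraps `prcomp`.  t-SNE plots are out of the
tested surface.

# Weakly supervised region localization

Pixel-accurate progenitor annotation is impractical, so supervision is
patch-level: `buildPatchDataset()` tiles wells (512-px patches at 50%
overlap in the published cardiac setting; both are parameters) and labels a
patch positive when ≥ 30% of its mask is dark gray, negative when the mask
is black only, and discards the rest.  The definitive-endoderm variant
labels against a binary SOX17 mask — obtained by `maskFromFluorescence()`,
binarization plus morphological closing — with a 20% positive threshold and
"no positive pixel" as the negative rule.  Light-gray ("likely") regions
count toward ground truth in evaluation but not toward the 30% labeling
rule, which names dark gray only.

The classifier backbone is pluggable behind a three-part contract: class
probabilities, activations $A^k$ of the last convolutional layer before
global average pooling, and gradients of the positive-class pre-softmax
score $y_+$ with respect to them.  The tested desk backbone is a small
three-block CNN trained with Adam; the published large-residual-network
settings (300 epochs, mini-batch 6, learning rate 3e-5) are carried as the
`"paper"` preset for fidelity runs with an external backbone.  Gradient
access is exact because the CNN machinery in this package computes its own
backward passes (verified against finite differences in the test suite).

Localization uses gradient-weighted class-activation maps:

$$\alpha_k = \frac{1}{Z}\sum_i\sum_j \frac{\partial y_+}{\partial A^k_{ij}},
\qquad \mathrm{heatmap} = \mathrm{ReLU}\Big(\sum_k \alpha_k A^k\Big),$$

with all-zero maps for patches predicted negative.  Maps are normalized to
0–255 per patch (an all-zero map stays zero) and binarized at 10; the
normalize-then-reconstruct order follows the published sentence order, and
whole-well reconstruction combines heatmaps by mean and binaries by logical
OR (`predictRegions()`).  `segmentationMetrics()` implements the six
printed pixel metrics; degenerate images (all or no ground-truth positives)
are flagged discarded.  `rankWells()` orders screening wells by predicted
committed-region fraction with the published defaults (top 40, candidate
threshold 40%), ties broken by well id, controls carried through unranked.

# Bright-field to fluorescence translation

`buildTranslator()`/`trainTranslator()` implement the conditional-
adversarial image translator: a U-Net generator with skip connections,
nearest-neighbor upsampling followed by convolution (avoiding checkerboard
artifacts), instance normalization, and a final convolution over the
concatenation of decoder features, encoder features and the input itself
with output clamped to [0,1] — the direct input path keeps the identity map
exactly representable and avoids output-nonlinearity saturation.  The
discriminator is a patch discriminator (stride-2 4×4, stride-2 3×3,
stride-1 3×3 convolutions) whose per-pixel receptive field is exactly
16×16; the build verifies this empirically by backpropagating a unit
gradient from one interior score pixel and measuring the input support, and
refuses to build otherwise.

The objective is $\lambda\,\mathcal{L}_{L1} + \mathcal{L}_{cGAN}$ with
$\lambda = 100$; the reported total equals that decomposition exactly at
every epoch, and the L1 curve is additionally logged at the conventional
1/5 display scale with raw values stored.  The adversarial term is active
only until `ganDisableAfter`, after which the discriminator is frozen
(parameter hashes are recorded at freeze time and at the end and must
match).  The learning rate holds for the first half of the epochs and
decays linearly to zero in the second half.  The `"paper"` preset carries
the published configuration (256-px patches, 1260 patches/epoch, mini-batch
16, 2000 epochs, Adam $\beta_1 = 0.5$, lr 2e-4); the `"desk"` preset
(64-px patches, 4 base channels, 32 patches/epoch, 30 epochs) is the tested
CPU path.  Randomness from dropout is available in the generator bottleneck
and off by default at inference.  `evaluatePixelCorrelation()` resizes both
images to 512², reports the pixel Pearson correlation (undefined, reported
as NA, for constant images) and a joint intensity histogram with counts per
100.

# The synthetic well generator

Every module is testable offline because `generateWell()`,
`generateStream()` and `generateBatch()` produce wells with the statistical
structure the models assume:

* **Colonies** are ellipse-like regions with smoothed random boundary
  perturbations (low-order Fourier modes on the radius); interiors carry
  band-limited noise texture, and committed ("fated") regions carry a
  finer, higher-variance texture (default contrast ratio 2.5) — this is
  what gives keypoint detectors, entropy filters and the patch classifier
  real signal.  A one-pass radius calibration keeps achieved colony
  coverage close to its drawn target (40–60% of the well).
* **Dose response** is a Gaussian bump in log concentration centered at a
  line-specific optimum: the committed fraction of the colony area equals
  `maxDarkFraction` (default 0.6) times
  $\exp(-(\log c - \log c^\ast)^2 / 2\sigma^2)$ with $\sigma = 0.25$.
  These defaults make the generated titration curves unimodal and give the
  20% labeling rule three classes over the default 2–10 μM grid, the
  regime the dose model is built for.  Noise enters the fluorescence
  rendering, not the latent curve.
* **Morphology coupling**: fluorescence intensity is modulated by a latent
  colony quality, unimodal in achieved coverage and peaked at 50%, so the
  0 h morphological profile genuinely predicts the final efficiency index —
  the structure the colony forest is asked to recover.
* **Streams** warp the 0 h frame by a per-frame contraction proportional to
  dose (2% per frame at the top of the concentration grid) while colony
  regions brighten linearly in time and dose; a dose of 0 is accepted as
  the no-contraction surrogate and yields ten identical frames.  Colony
  area is therefore non-increasing, brightness non-decreasing, and boundary
  displacement grows with dose by construction.
* **Masks** label committed regions dark gray with a thin light-gray rim,
  and everything else black; fluorescence positives lie inside dark-gray
  regions.
* All randomness flows through one master seed via a deterministic fan-out
  (`deriveSeed()`), with the caller's RNG state restored afterwards; a
  fixed plan and seed reproduce outputs bit for bit.

Default sizes: stream frames are 486 px — the smallest side that admits the
full box-counting schedule — and colony-model wells 256 px.  The test suite
exercises the pipelines at the sizes the recovery checks prescribe
(200 wells for the dose model, 500 for the colony forest, a handful of
wells for localization); these are the package's chosen desk-scale study
conditions.

What the generator does *not* emulate: photorealistic cell rendering,
z-stacks, autofocus artifacts, well-edge vignetting, debris, and
line-to-line morphology differences beyond the optimum shift.  Passing
recovery tests therefore demonstrates that the estimators and models
implement their contracts and can extract planted structure of realistic
geometry and contrast — not that they reach any particular accuracy on real
microscope data, which depends on dataset scale and backbone capacity far
beyond the desk configuration.

# Numerical conventions and degenerate inputs

Empty masks yield zero statistics with warnings rather than errors; empty
keypoint sets yield zero vectors; a labeling with no qualifying
concentration is an explicit "no optimal range" error; concentrations with
no wells are omitted from Deviation Scores; constant images make the pixel
correlation NA with a message.  Strict inequality $I > \alpha$ is used at
the efficiency threshold, and flow vectors are discarded at magnitude ≤ 4,
both as printed.  Solver tolerances: glmnet defaults with the per-preset
penalty; k-means with 50 iterations and a fixed seed; Adam with the
published betas.  The standard deviation in descriptor summaries uses
population (n) normalization; single-keypoint images get zero standard
deviation.

# Known limitations

* The keypoint descriptor families and the block-matching flow are
  contract-compatible stand-ins written for this package, not bindings to
  the classical implementations; absolute feature values will differ from
  OpenCV's even though layouts, invariances and downstream behavior match.
* The desk CNN backbone is far smaller than a deep residual network; it is
  the tested path, and the published presets are carried as configuration
  for environments that can train at scale.
* Components connected only through diagonal pixel contact are merged for
  labeling, but their traced outer contour covers the part containing the
  first boundary pixel; for the smooth colony shapes this package targets
  the effect is negligible.
* The acquisition-plan helper covers tile-count arithmetic and coordinates;
  microscope control, stitching and CZI parsing are out of scope.
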