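---
title: "Methods: hyperspectral bruise detection and quantification on strawberry phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral bruise detection and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strawbruise)
```

## The problem

Impact bruises on strawberries are often invisible at harvest and develop
over storage. Hyperspectral imaging sees them early: bruised tissue
reflects less light across the visible and infrared, with absorption
deepening near 675 nm as pigments degrade and near 970, 1191 and 1873 nm
as water redistributes through ruptured cells. `strawbruise` implements
the full chain from raw line-scan cubes to a per-pixel bruise map and a
scalar bruised-area ratio, together with a synthetic phantom generator
that stands in for camera data so that every stage can be validated with
exact ground truth.

This vignette records the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open.

## The phantom generative model

A scene (`phantom_scene`) is an elliptical fruit, an optional elliptical
bruise contained in it, achene speckles, and an optional rectangular leaf
region disjoint from the fruit. A spectral class model
(`spectral_class_model`) maps each ground-truth pixel class to a
reflectance spectrum:

* **Baseline** `b(λ)`: a monotone-Hermite spline through ten control
  points giving low reflectance below 500 nm, a mild valley near 675 nm,
  a broad NIR plateau, and a gentle decline through the SWIR water bands —
  the qualitative shape of measured strawberry reflectance. The knots are
  free parameters; the defaults are in `default_baseline_knots()`.
* **Shared absorption valleys**: Gaussians at 675, 970, 1191 and 1873 nm
  (σ = 14–45 nm, depths 0.02–0.05 reflectance units) subtracted from the
  baseline for *all* classes.
* **Bruise effect**: a global multiplicative depression per class times
  the shared curve, minus severity-scaled extra absorption depth at the
  four centers. Both deepen linearly with storage hours
  (`storage_gain`, default 0.0015 per hour). Default depressions are
  1.0 / 0.93 / 0.80 for Intact / Bruised I / Bruised II. The steps are
  deliberately **unequal**: damage accelerates with impact energy (the
  treatments themselves are 0, 0.06 and 0.19 J), and equal steps combined
  with severity-linear absorption would make the three class prototypes
  exactly collinear — a degenerate geometry in which one-hot linear
  discriminants (PLS-DA, least squares) provably cannot recover the middle
  class, which no real spectral dataset exhibits.
* **Noise**: a per-spectrum multiplicative scatter factor `(1 + ε)`,
  ε ~ N(0, `scatter_sd`²), plus additive per-band noise N(0, `noise_sd`²)
  — the standard chemometric decomposition into scatter and detector
  noise. Defaults 0.01/0.01; the validation conditions below use 0/0.
  Simulated reflectance is clipped to [0, 1].
* **Achenes** are dark speckles at 0.3 × the fruit baseline, placed fully
  interior to the fruit silhouette (centers drawn from the ellipse with
  axes shrunk by the speckle radius + 2 px): a speckle straddling the
  silhouette rim would be half background, which does not occur on the
  imaged fruit face.
* **Leaves** combine a low red reflectance with a sigmoidal NIR shoulder
  at 715 nm, so their NDVI at the classical 670/800 nm pair is ≈ 0.79 —
  above the 0.6 construction floor — while fruit of every class and
  storage time stays below 0.4.

With `target_bruise_ratio = r`, the bruise ellipse takes the fruit's
shape scaled by `sqrt(r/100)`, so the analytic area ratio
`πa_b b_b / (πa_f b_f)` equals `r` and the rasterized ratio converges to
it as resolution grows (bookkept, never re-solved). All randomness flows
through one seeded generator passed explicitly; identical seeds give
bit-identical cubes.

What the phantom deliberately does **not** emulate: radiative-transfer
realism, surface texture and glare, camera co-registration error, or
SWIR striping. Passing the phantom validation therefore demonstrates
correctness of the *pipeline machinery* — segmentation logic,
preprocessing symmetry, training, per-pixel inference, area bookkeeping —
not field performance on real fruit.

## Calibration and I/O

Reflectance calibration is `R_cal = (R_raw − R_D)/(R_W − R_D)` per pixel
and band; white/dark frames may be full cubes, per-column (line-scan)
matrices, per-band vectors, or scalars, and all broadcast. Calibrated
values are **not** clipped to [0, 1]: sensor noise can legitimately exceed
the white panel, and clamping is left to downstream choice. A zero
denominator anywhere aborts with the offending band indices. ENVI cubes
are read/written in BSQ/BIL/BIP interleaves (float32, little-endian) with
the wavelength list in the header; axes in memory are always
(row, col, band).

## Segmentation

* **Fruit**: Otsu threshold of the band image nearest 647 nm — the
  wavelength with stable fruit/background contrast across bruise levels —
  over a 256-bin histogram; foreground is the brighter class; candidate
  thresholds are bin edges and ties go to the lowest. Refinement is
  opening then closing with disk structuring elements (radius 2 px each),
  keeping the largest connected component, and filling holes. Enclosed
  holes are additionally filled once *before* the opening: achene
  clusters fall below the fruit/background threshold, and opening would
  otherwise erode a rim-adjacent hole into an open bay that the final
  hole fill cannot recover.
* **Achenes**: black-hat transform (closing − image, disk radius 3 px)
  thresholded at 0.1, restricted to the fruit mask. The black-hat
  responds only to dark-on-bright features smaller than the structuring
  element, which is exactly the achene geometry at 647 nm.
* **Leaves**: NDVI = (R₈₀₀ − R₆₇₀)/(R₈₀₀ + R₆₇₀) > 0.4, with NDVI
  defined 0 where the denominator vanishes. The band pair and threshold
  are the classical vegetation-index defaults.

The ROI is derived, never stored: `fruit ∧ ¬achene ∧ ¬leaf`. Morphology
is delegated to `EBImage`; the Otsu maximization is implemented directly
because its equivalence to an exhaustive between-class-variance search is
one of the package's oracle checks.

## Preprocessing and splitting

Per-fruit signatures are the arithmetic mean spectrum over the ROI. The
pipeline is band trimming (Vis-NIR keeps 380–1010 nm, SWIR 1000–2000 nm),
a 5-point moving average with truncated (shrinking) windows at the edges
so length is preserved, then a first derivative by central differences
(one-sided at the ends) in reflectance per nm. Smoothing and derivative
are listed as separate steps deliberately — a Savitzky–Golay kernel would
fuse them. The derivative removes additive baseline offsets exactly.

The Kennard–Stone split is fully deterministic: the first two calibration
picks are a maximally distant pair (Euclidean), each later pick maximizes
its minimum distance to the selected set, ties always resolve to the
lowest row index, and the calibration size is `round(n × 2/3)`. By
default the algorithm runs within each class, keeping classes balanced
2:1 across both sets; `per_class = FALSE` pools. The SWIR grid uses 146
evenly spaced bands over 1000–2000 nm; the nominal 6.2 nm instrument
resolution would imply a different count, and the even grid is the
package's resolution of that inconsistency.

## The classifier

Efficient1DNet processes a length-L spectrum through a stem
`Conv1D(1→C₀, k=3, s=2, p=1) + BN + SiLU`, a ladder of MBConv blocks, and
a head `GAP → dense → softmax`. Each MBConv block is:

1. pointwise expansion `C → Ĉ = eC`, BN, SiLU;
2. depthwise convolution (kernel k, stride s, padding (k−1)/2), BN, SiLU;
3. squeeze-excitation: `a = σ(W₂ ReLU(W₁ GAP(H₂) + b₁) + b₂)` with
   bottleneck `m = round(0.25 Ĉ)`, applied channel-wise;
4. pointwise projection `Ĉ → C′`, BN, no activation;
5. residual `Y = U + V` iff `s = 1` and `C′ = C`.

The compound-scaling helper exposes the EfficientNet rule
`(d, w, r) = (α^φ, β^φ, γ^φ)` with the constraint `α·β²·γ² ≈ 2`
(tolerance 0.1) checked at call time.

**Reference configuration.** The architecture family is fixed by the
module inventory (expansion-1 first block, expansion-6 blocks with
kernels 3 and 5, SE ratio 0.25), but the exact widths are not; the
package's reference config was calibrated once by searching that family
for an exact trainable-parameter total of **405,098** at L = 440, 3
classes, and then frozen: stem C₀ = 16 and block widths
24, 24, 24, 32, 32, 88, 151 (strides 1,2,1,2,1,2,1). Parameters are
counted analytically (convolution kernels without bias, BN affine pairs,
SE weights and biases, classifier weight and bias) and cross-checked
against the scalar total of an instantiated weight set. A compact
two-block variant (`e1d_compact_config`, ~5.7k parameters) is provided
for phantom-scale work where the full capacity is unnecessary.

**Training protocol.** Adam at 5×10⁻⁵, cross-entropy, batch 32 with the
last incomplete batch kept, training batches shuffled, 100 epochs,
5 independent repeats from seeds 0–4, and selection of the repeat with
the highest final-epoch validation accuracy (ties to the lowest index; a
`best`-epoch mode is available since the selection epoch was an open
choice). BN uses ε = 10⁻⁵ and momentum 0.1; convolutions use
Kaiming-normal initialization, BN starts at scale 1 / shift 0. Labels
encode Intact = 0, Bruised I = 1, Bruised II = 2; storage hours sort
ascending. Input spectra are autoscaled per band (centered, unit
variance, fitted on the calibration rows and stored on the model):
first-derivative spectra are of order 10⁻³ reflectance/nm, far below the
activation scale the initialization assumes, and no variant of the
network trains at the protocol learning rate without this standard
chemometric step.

The entire engine — im2col convolutions, depthwise and pointwise kernels,
BN in train/eval modes, SiLU, SE, softmax/cross-entropy, backpropagation,
Adam — is implemented in R. Its gradients are verified against central
finite differences at every weight leaf in the test suite, and the MBConv
forward pass against a straight-line scalar-loop hand computation.

## Baselines

PLS-DA is implemented from first principles: one-hot class coding,
NIPALS-style sequential extraction of latent components maximizing X/Y
covariance on centered data (dominant direction via SVD of `X'Y`),
deflation, and the argmax-of-indicators decision rule (the rule itself
was unspecified; argmax is the common choice). With as many components as
the data rank it reproduces least-squares predictions, which is its
oracle check. The SVM baseline delegates to `e1071::svm` (RBF kernel,
cost 1, γ = 1/p — unstated in the protocol, so documented defaults). The
1D-CNN reference is a plain three-stage conv/BN/SiLU net with a wide
dense head (≈ 746k parameters at default width — deliberately heavier
than the MBConv net, matching the qualitative capacity ordering); the
LSTM reference reshapes the spectrum into 20 timesteps × ⌈L/20⌉ bands and
runs a single 64-unit LSTM with mean-pooled hidden states (≈ 22k
parameters at defaults — the lightest of the three networks), keeping
backpropagation-through-time shallow. Both
train through the same Adam/cross-entropy loop and autoscaler as the main
model. All baselines consume the same split `spectral_dataset` and emit
predictions through one interface.

## Quantification

Pixel-level inference reuses the *training* preprocessing per pixel —
trim, smooth, derivative along the spectral axis, then the model's stored
autoscaler — a symmetry the pipeline enforces rather than assumes. Both
bruise severities map to "bruised"; achene- and leaf-covered pixels are
"excluded"; off-fruit is "background". The bruised-area ratio is
`100 · n_bruised / (n_bruised + n_intact)`: excluded pixels are outside
the classification and outside the denominator by default, with
`include_excluded = TRUE` available because the real-data denominator
("total pixel count of the strawberry") is ambiguous about seeds. Maps
render blue/orange/green/black with exactly one color per class, so the
class map is recoverable by inverse palette lookup. Impact energy is
`E = mgh` with g = 9.8 m/s² (this value reproduces the printed treatment
energies at two decimals); ellipse area is `S = πab`.

MAE and RMSE between true and estimated ratios use their plain
definitions; MAE ≤ RMSE always (Jensen), and the suite asserts it on
random pairs.

## Validation design and problem sizes

The test suite validates each operation against independent oracles
(exhaustive Otsu search on random 64×64 images; brute-force max–min
selection for all splittable n ≤ 8; scalar-loop MBConv arithmetic;
closed-form regression for PLS-DA; numerical gradients for the whole
network) and then runs the pipeline end to end: a noise-free separable
dataset of 300 mean spectra (100 per class, 440 bands) is preprocessed,
split 2:1, and used to train the compact configuration for 40 epochs
(1 repeat) at the protocol learning rate, reaching 100 % validation
accuracy; 20 phantom cubes (72×72 px, 440 bands) with true bruised ratios
spanning 5–40 % are then segmented, mapped and quantified, requiring
|estimated − true| ≤ 3 percentage points on every cube. On noise-free
phantoms the realized error is 0.0 points, so the margin absorbs the
rasterization and mask-boundary effects it was budgeted for. These sizes
are the package's chosen validation conditions: large enough that every
stage processes realistic structure, small enough to re-run routinely.

Determinism is asserted at byte level: identical seeds must reproduce
splits, training histories, weights and rendered maps exactly.

## Known limitations

* The phantom's class structure is low-rank by construction; real
  within-class variability (fruit size, orientation, ripeness) is
  represented only by scalar scatter noise. Accuracies on phantoms say
  nothing quantitative about field accuracy.
* The reference architecture reproduces the published parameter budget,
  not necessarily the original layer-by-layer stack, which was never
  printed.
* Training is pure R and single-threaded: the reference model trains at
  phantom scale in minutes, not the seconds a GPU framework would take;
  the compact configuration is the practical default for simulation
  studies.
* Geometric co-registration of the two cameras, multi-fruit scenes, and
  calyx-specific modeling are out of scope.
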