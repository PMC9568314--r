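---
title: "Methods: simulating and recognising CT artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and recognising CT artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctartsim)
```

# The problem and the pipeline

Artifacts — image structures with no anatomical counterpart — are a routine
failure mode of computed tomography. For sinus and skull-base imaging the
three classic culprits are patient motion (blur/misregistration), detector
miscalibration (concentric rings centred on the rotation axis), and beam
hardening (dense bone preferentially absorbs low-energy photons, darkening
and shadowing the structures behind it). `ctartsim` implements a four-stage
pipeline for studying whether such artifacts can be recognised
automatically from the image alone:

1. generate a seeded cohort of head-CT-like phantoms;
2. derive three artifact variants of every phantom with pure
   image-to-image simulators;
3. fingerprint every image by its leading singular values;
4. train and cross-validate a binary SVM per artifact class against the
   originals, reporting ROC/AUC and confusion-matrix metrics.

This vignette records the models behind each stage, the tunable parameters
and their defaults, the numerical conventions, and the design choices that
were genuinely open.

# Synthetic phantoms

No annotated artifact corpus is bundled, so the study set is synthetic. A
phantom (`phantom_spec()`, `generate_phantom()`) is built from geometric
primitives chosen to match the *statistical* structure of a sinus CT slice,
not its anatomy:

* a closed elliptical **bone shell** at intensity 0.9 (unit scale) —
  the brightest structure, as calcified bone is in CT;
* an interior **soft-tissue** fill at 0.35;
* dark **air-filled cavities** (intensity 0.05–0.08) standing in for the
  paranasal sinuses, with layouts varying by `plane_style`
  (axial/coronal/sagittal) purely cosmetically;
* **background air** at 0;
* additive Gaussian **acquisition noise**, default `noise_sd = 0.02`,
  clipped to `[0, 1]`.

`generate_image_set()` emulates a cohort of different patients by jittering
the skull centre and axes uniformly by ±5 % under per-image sub-seeds
(`seed + index`), so a set is reproducible from a single integer. The
default cohort size is 43 on a 256×256 canvas — a realistic single-site
series, and large enough that 4-fold cross-validation folds stay balanced
(4 classes × 43 images = 172, splitting into 4 groups of 43 by class).

Ellipse membership is evaluated at pixel centres in 0-based (row, col)
coordinates, which makes rasterization unambiguous and lets tests check
cavity areas against a brute-force evaluation of the ellipse inequality.

**What the phantoms do not model:** projection physics. There is no Radon
transform, no sinogram, no reconstruction filter. Consequently a classifier
that separates these phantoms perfectly has been shown to detect *the
simulated intensity perturbations*, not the reconstruction-domain texture
of clinical artifacts; transfer to real scanner data is an open question
that only real data can answer.

# Artifact simulators

All three simulators preserve image dimensions and the unit intensity
range, and are deterministic.

## Motion

Patient motion between projections is reduced to its simplest surrogate:
an in-plane rotation by the 2-D rotation matrix
\[
R(\theta) = \begin{pmatrix}\cos\theta & -\sin\theta\\ \sin\theta & \cos\theta\end{pmatrix}.
\]
`simulate_motion()` applies it by inverse mapping about the geometric
centre `((H−1)/2, (W−1)/2)`: each output pixel samples the source image at
the back-rotated location, with bilinear (default) or nearest-neighbour
interpolation; positive θ is counter-clockwise in standard orientation,
and out-of-frame samples take `fill_value` (default 0, the dark CT
background). With nearest interpolation and θ a multiple of 90° on a
square image the operation is an exact index permutation — which also
preserves the singular-value spectrum exactly, a deliberate stress case
showing that recognisability of rotations comes from interpolation and
frame effects at generic angles, not from trivial spectral changes. In the
full experiment each image receives its own seeded angle, magnitude
uniform in [5°, 25°] with random sign: small enough to look like motion
misregistration, large enough that features genuinely differ.

## Concentric rings

Detector-calibration rings are circles
\((x-h)^2 + (y-k)^2 = r^2\) around a common centre. `simulate_rings()`
realises them as annuli of fixed width: pixels whose Euclidean distance
from the centre lies in `[r − w/2, r + w/2]` get an additive signed offset
(or are replaced, in `replace` mode); no other pixel changes. Radii must be
strictly increasing, with spacing at least the ring width, so annuli never
overlap and the multi-ring result is exactly the union of the single-ring
results. The default layout (`default_ring_spec()`) is 4 rings spanning
15–45 % of the smaller image dimension, width 2 px, offset +0.25 — the
classic bright-ring appearance.

## Beam hardening

The visual signature of beam hardening is that the whites are attenuated,
obscuring internal bone structure. The simulator first (optionally)
binarizes the image by Otsu's method to isolate the bright foreground,
then applies a soft-knee law to every pixel above the attenuation
threshold τ:
\[
\text{out} = \text{in} - s\,(\text{in} - \tau), \qquad \text{in} > \tau,
\]
with τ = 0.4 on the unit scale and strength `s` in `[0, 1]`. The law is
the simplest monotone attenuation with an explicit strength parameter and
the stated threshold as its knee: it never brightens a pixel, is pixel-wise
monotone, and at `s = 1` maps every bright pixel exactly to τ. The default
`s = 0.5` darkens 0.9-bone to 0.65 — visible but not destructive. The
output is the attenuated *grayscale* image (not the binary mask): the
recogniser should see an image a radiologist would see. Both τ and `s` are
config-exposed.

## Otsu's threshold

`otsu_threshold()` works on a 256-level histogram (`gray_histogram()`
quantizes unit intensities by rounding to `g = round(255·v)`). With
\(P_0(t)=\sum_{g\le t} p(g)\) and \(P_1(t)=1-P_0(t)\), it returns the
integer `t` maximizing the between-class variance
\(P_0 P_1 (\mu_0-\mu_1)^2\) — equivalently minimizing the within-class
spread. Two conventions are fixed deliberately:

* **tie-break**: the *smallest* maximizing `t`. Histograms with empty
  valleys (e.g. well-separated bimodal images) have a plateau of equally
  optimal thresholds; picking the smallest makes the result deterministic
  and exactly comparable to an exhaustive search, which the tests do on
  every tried histogram. Other implementations pick other points on the
  plateau; agreement with them is therefore only up to the plateau.
* **scale**: thresholds are integers on the level scale; image-level code
  uses `t/255` on the unit scale.

A single-level histogram has no two-class split and raises a
degenerate-input error.

# Singular-value features

`singular_values()` returns the full spectrum of the intensity matrix
(descending, length `min(H, W)`); it satisfies the Parseval identity
\(\sum_i \sigma_i^2 = \lVert A\rVert_F^2\) and is checked against a
Gram-matrix eigensolver in the tests. `extract_features()` zeroes entries
below `null_tol · σ₁` — treating them as numerical nulls — and keeps the
leading `k`. Defaults `k = 32`, `null_tol = 1e-10`: the spectrum of a
256×256 phantom decays fast, and 32 values keep the SVM problem tiny while
retaining all the variance the simulators touch; both are config-exposed
since no principled universal value exists.

Equal feature length requires equal matrix size; a decomposition of the
matrix does not by itself guarantee that, so `build_feature_dataset()`
enforces one canvas explicitly, resizing bilinearly to 256×256 when inputs
are mixed. Features are scale-equivariant (scaling an image by `c` scales
every singular value by `c`), so the SVM stage standardizes per dimension —
using training-fold statistics only, to avoid leakage into held-out scores.

# SVM recognition

Each comparison is strictly binary: originals (mapped to −1) versus one
artifact class (+1), so positive decision scores always mean "artifact
detected". `train_svm()` solves the soft-margin dual with libsvm's SMO
solver (via e1071) at tolerance 1e-6 and stores the decision function
explicitly — support vectors, signed dual coefficients
(\(|\alpha_i| \le C\)), bias — so `decision_scores()` evaluates
\(f(x) = \sum_i \alpha_i y_i K(x_i, x) + b\) from `kernel_eval()` alone and
models serialize to self-describing JSON. Kernels: linear \(u\cdot v\),
polynomial \((\gamma u\cdot v + c_0)^d\), Gaussian
\(\exp(-\gamma\lVert u-v\rVert^2)\). The singular-value features of
artifacted versus original images are not linearly separable in general,
so the Gaussian kernel is the default. Hyperparameters follow common
heuristics — `C = 1`; `γ = 1/(k · var(features))` computed on the
standardized training features when unset; degree-3, `coef0 = 1` for the
polynomial — and all live in the config; no tuning was performed.

# Validation design

## Splits

`kfold_split(n, k, seed)` shuffles indices under the seed and deals them
into folds whose sizes differ by at most one (172 at `k = 4` gives four
folds of 43); `loo_split(n)` is the leave-one-out limit. The repeated
protocol (`cv_spec()`, default 30 iterations) reseeds iteration `i` with
`seed + i`, so the whole 30-iteration experiment is reproducible from one
integer.

## Paired folds

The artifact images are *derived from* the originals: image `i` and its
three variants share geometry and noise. With weak artifacts a plain
row-level split can put an original and its near-identical derivative on
opposite sides of a fold boundary, letting the model read the held-out
label off the training twin — with *zero-strength* artifacts this twin
memorization actually inverts the ranking (the held-out twin is pulled
toward its partner's opposite label) and biases AUC well below chance.
Cross-validation therefore splits over *source images* whenever a grouping
is available (`groups` argument or `group` column): all derivatives of one
source are held out together, the standard grouped-CV design for paired
data. At null effect the grouped design measures exactly chance; with
signal it is unchanged.

## ROC, AUC and confusion metrics

`roc_curve()` sweeps the decision threshold from above the largest score
downward (predict positive when `score ≥ c`), recording the true-positive
fraction against the false-positive fraction at every distinct score. AUC
is the trapezoidal integral, which with ties counted half equals the
Mann–Whitney probability that a random positive outranks a random
negative; the tests assert this identity exactly on randomized inputs. AUC
is allowed the full `[0, 1]` range — worse-than-chance rankings exist and
are flagged on printing rather than clamped to `[0.5, 1]`.

Confusion counts pool all out-of-fold predictions at decision threshold 0
(the SVM boundary; the operating point is config-exposed since no
principled choice exists without a cost model). Precision is
`TP/(TP+FP)`, recall `TP/(TP+FN)` — the standard definitions; texts
occasionally misprint recall's numerator as FN, but only `TP/(TP+FN)`
measures the fraction of genuine artifacts recognised — and the F-score is
their harmonic mean. Per-iteration AUC dispersion is reported both as
standard deviation and max−min, since "variation between iterations" has
no canonical measure.

# Numerical conventions

* Intensities live on `[0, 1]` internally; 8-bit PNG export quantizes by
  `floor(255·v + 0.5)` (round half away from zero), and a written image
  read back reproduces the quantized matrix bit-exactly.
* RGB input is converted by the NTSC luma weights
  `0.299 R + 0.587 G + 0.114 B` (the perceptual brightness weighting),
  with 0–255 input detected and renormalized.
* Rotation/resize coordinates: 0-based pixel centres, row axis down,
  centre `((H−1)/2, (W−1)/2)`.
* All stochastic stages draw from a private seeded RNG stream and restore
  the caller's RNG state; sub-seeds are `base + offset` kept below 2³¹.
* Degenerate inputs fail loudly: single-class training data, single-level
  histograms, single-class ROC labels, undefined precision/recall all
  raise validation errors rather than returning NaN.

# Problem sizes

The bundled tests exercise the full pipeline at the study scale the
package defaults to — 43 phantoms per class, 256×256, 30 iterations of
4-fold CV — which completes in seconds; unit and property tests use
smaller canvases (32–96 px) where the oracles are brute-force loops.
`scripts/acceptance.R` reruns the full study and writes every headline
number it computes.

# Known limitations

* Phantoms are geometric, not physical: no projection-domain simulation,
  no reconstruction kernel texture, no metal, misalignment or
  undersampling artifacts (listed in the field's taxonomies but given no
  implementable procedure here).
* The recognisers saturate on default-strength synthetic artifacts; the
  interesting regime for method comparison is weaker strengths, which the
  config exposes.
* DICOM input is not implemented; the I/O layer reads and writes PNG.
  Clinical pipelines should convert upstream.
* Singular values are a global fingerprint: they discard all spatial
  phase, so localized artifacts that barely move the spectrum (a single
  faint ring) are intrinsically hard for this feature family.
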