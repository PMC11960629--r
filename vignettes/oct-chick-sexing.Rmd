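---
title: "Methods: simulated SD-OCT imaging and CNN-based chick sexing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated SD-OCT imaging and CNN-based chick sexing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octsex)
```

`octsex` packages a complete measurement-and-classification chain for
OCT-based chick sexing. This vignette is the package's account of the
science inside it: the models, their assumptions, the tunable parameters
and why they default to what they do, and the places where the design was
genuinely open and a choice had to be made.

## The discriminative anatomy and its phantom

The biological signal is a count: the everted chick cloaca shows a phallus
with three cones in males and two in females. `make_phantom()` encodes
exactly this. A phantom is a 2-D cross-section in physical units (µm): a
gently tilted tissue surface at 700–1100 µm depth, three sub-surface
layers (150–400 µm thick, backscatter reflectivity 0.15–0.45 with a
brighter 0.45–0.65 surface band), exponential depth attenuation
(0.8–1.8 × 10⁻³ µm⁻¹), and on the surface the sex-determining cones,
rendered as triangular wedges.

No published geometry exists for the cones, so the ranges are the
package's own and deliberately configurable: width 200–600 µm, height
150–400 µm, backscatter amplitude 0.7–1.0, neighbour spacing 700–1100 µm.
The guiding constraints were physical plausibility (sub-millimetre
structures an expert can just see), resolvability at the scanner's 4 µm
lateral pitch, and — the binding one — survival of the cone count through
the 13× downsampling to the network's 75 × 64 px input. Wedges much below
~150 µm blur into the surface after area-averaging and the class signal
disappears; that regime is reachable via `phantom_params()` and is used
deliberately as the "no recoverable signal" control in the acceptance
tests.

A cohort (`make_cohort()`) draws each chick's base anatomy once and then
jitters it per frame (±10 % cone sizes, ±50 µm lateral, ±30 µm surface
depth), emulating repeated scans at slightly different cloacal locations:
frames of one chick are correlated, chicks are not. This correlation
structure is what makes the chick-level split meaningful. A configurable
fraction of frames (default 5 %) has the cones fully occluded; these carry
the label `ambiguous`, are excluded from training, and constitute the true
`not_detect` class at evaluation.

## The SD-OCT forward model and reconstruction

`simulate_interferogram()` implements ideal spectral-domain OCT: the
source is a Gaussian spectral envelope sampled uniformly in wavenumber
(2048 samples by default), and a reflector at depth $z$ contributes a
fringe of phase $2kz$ to the detected intensity

$$I(k) = S(k)\,\bigl|\,1 + a \sum_z r(z)\,e^{2ikz}\bigr|^2 .$$

Assumptions worth stating: the spectrometer is ideal (no resampling error,
no sensitivity roll-off), dispersion is matched, and the sample arm is
weakly coupled ($a = 0.1$) so that the autocorrelation term
$a^2|\Sigma|^2$ stays an order of magnitude below the cross term. The
wavenumber spacing is tied to the depth grid by $\delta z = \pi/(N\,
\mathrm{d}k)$, so one FFT bin is one configured depth pixel and a
reflector at row $i$ of the reflectivity map reconstructs at row $i$ of
the image; the test suite asserts ±1 px.

`reconstruct_aline()` subtracts the reference-arm spectrum before the FFT.
Without this the DC peak dominates the image *and* — more insidiously —
becomes the per-image maximum that the normalization step divides by,
flattening all tissue contrast. The envelope is the FFT magnitude over
positive-depth bins.

The processing chain then follows the standard display convention:
per-image normalization by the maximum envelope amplitude (the maximum is
exactly 1.0 afterwards — floating-point division by the maximal element is
exact), and logarithmic compression into 8 bits. A bare description like
"a logarithmic transformation into 8-bit" admits many maps; the package
fixes

$$u = 255 \cdot \mathrm{clip}\!\bigl(1 + \mathrm{dB}(x)/|F|,\,0,\,1\bigr),
\qquad \mathrm{dB}(x) = 20\log_{10} x,$$

with floor $F = -50$ dB: full scale maps to 255, anything at or below the
floor to 0, and the map is monotone. −50 dB is a common soft-tissue
display range; it is a display choice, not physics, and is exposed as
`floor_db`.

**Source bandwidth.** The only spectral fact available is the centre
wavelength (840 nm) and the stated ~10 µm depth resolution. The default
bandwidth, 31 nm FWHM, is back-derived from the Gaussian coherence-length
formula $\delta z = (2\ln 2/\pi)\,\lambda_0^2/\Delta\lambda = 10.04\,$µm.
This is not assumed but measured: `axial_resolution()` places a single
reflector, reconstructs with 16× zero-padding, and measures the envelope
FWHM by linear interpolation; the acceptance suite requires agreement with
10 µm within 20 %.

**Speckle and noise.** Coherent imaging carries multiplicative speckle.
The package applies it on the envelope: each amplitude is multiplied by
$(1-s) + s\,R$ with $R$ unit-mean Rayleigh and $s \in [0,1]$ the
`speckle_scale` (default 0.15, a visibly granular but anatomy-preserving
level; 0 disables), plus an additive detector floor at 2 × 10⁻³ of the
envelope maximum. This is a phenomenological model — real speckle is
correlated with the resolution cell, whereas ours is i.i.d. per pixel —
which matters for texture statistics but not for the cone-count signal the
classifier uses.

**Geometry.** The acquisition is 1000 × 1000 px over 4 × 4 mm (4 µm/px
both axes); stored images are 1000 × 600 because only the top 600 depth
rows contain tissue — `depth_crop` reconciles the two sizes. Cohorts are
routinely scanned at reduced geometry (e.g. 200 A-lines at 20 µm pitch)
because every retained-count and split property is resolution-independent;
the full default geometry is exercised where the geometry itself is the
claim.

## Image preparation

* `enhance_image()` — 3×3 median denoising, linear percentile contrast
  stretch (1st–99th), unsharp masking (gain 0.5, σ = 1 px Gaussian). All
  three are no-ops on flat input and individually disableable; the method
  tags are validated.
* `quality_select()` — stands in for the manual "keep the clearest 40 of
  50". The score is the mean absolute gradient within the tissue band
  (rows whose mean exceeds a small threshold, padded so band edges count).
  Blank or structureless frames score 0 and drop first; ties break by
  frame index so selection is deterministic.
* `augment_image()` — label-preserving rotation (default ±15°, bilinear,
  about the centre), optional horizontal flip, brightness normalization to
  a target mean. Rotation range and flip axis are conventions, not
  reported facts; they are configuration, and augmentation is applied to
  the *training split only, after splitting* — the other order would leak
  augmented copies of test frames into training.
* `resize_image()` — exact area-weighted resampling (row-stochastic
  overlap-weight matrices applied on both axes). For integer factors this
  is block averaging, which preserves the energy of a few-pixel bright
  cone at 13× reduction far better than nearest-neighbour or bilinear
  sampling; resizing to the own size is the identity matrix, literally.
  Sizes are printed width-first ("75x64" = 75 wide × 64 tall) and
  `parse_size()` is the single decoder of that convention.
* `split_dataset()` — stratified with largest-remainder quota allocation,
  so the overall train count is exactly `round(n ·
  fraction)` (1200 → 960/240) regardless of how strata round
  individually. Both split granularities are provided: `by_image`
  (matches the printed 960/240 arithmetic) and `by_chick` (24/6 chicks at
  the defaults; no chick on both sides). Which one the original study
  used is not determinable — both yield 960/240 — so the package defaults
  to the leakage-safe `by_chick` and records the other as an option.

## The classifier

`cnn_fit()` trains the compact architecture: three conv(3×3, stride 1,
"same" zero padding, ReLU) + maxpool(2×2, stride 2) blocks with 32, 64,
128 filters; 25 % dropout; flatten (for 75 × 64 input:
37×32 → 18×16 → 9×8, features 9·8·128 = 9216); dense 256 with ReLU; 50 %
dropout; 2-unit softmax. Categorical cross-entropy is the loss — the
natural partner of a softmax output, though any description naming only
the activation leaves this open. Class indexing is fixed (0 = female,
1 = male) and asserted in the manifest codec and the model sidecar.

The numerics are the package's own RcppArmadillo kernels: im2col + GEMM
convolutions, argmax-tracking pooling, inverted dropout, and a backward
pass that the test suite checks against central finite differences at
1e-4. Training is plain minibatch Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8)
with defaults lr = 1e-4, batch 128, ≤1000 epochs. Weight init is He-normal
under a fixed seed; shuffling and dropout draw from R's RNG, so a fit is
deterministic given (data, config, seed) on a given BLAS.

**Early stopping and validation.** Training halts when validation loss
has not improved (strictly) for `patience` = 50 consecutive epochs, and
the best-validation weights are restored. The validation set is a
stratified 10 % hold-out *from the training split* — never the test set;
descriptions that conflate "validation" and "test" are resolved by keeping
them separate. The stopping rule is a pure function
(`stop_epoch_for()`), so its boundary behaviour (constant loss ⇒ stop at
epoch patience + 1) is testable in isolation; a zero learning rate is
deliberately permitted to freeze the network and exercise the rule
end-to-end.

**The `not_detect` outcome.** The evaluation surface has three outcomes,
but a 2-unit softmax can only produce two. How the third arose in the
original workflow is not recoverable (threshold? operator veto?); the
package operationalizes it explicitly as a confidence rule: predict
`not_detect` when the winning probability is below τ. The default
τ = 0.6 keeps the class reachable but rare; τ ≤ 0.5 provably disables it
for binary softmax (the winning probability is always ≥ 0.5), which the
tests assert. τ is a first-class parameter everywhere it matters.

## Evaluation

`confusion_matrix3()` tallies truth × prediction over (female, male,
not_detect); occluded frames are true `not_detect`. From the matrix,
`classification_metrics()` computes per-class precision, recall and F1
(defined as 0 where a denominator vanishes), macro averages over classes
with nonzero support (an empty class would otherwise drag the macro mean
with undefined values — the chosen convention excludes it and gives it
zero weight in the weighted mean), support-weighted averages, and
accuracy. Two algebraic identities serve as standing cross-checks:
weighted recall equals accuracy whenever every evaluated sample's true
class is among the averaged classes, and F1 never exceeds the larger of
precision and recall. The implementation is verified against a
brute-force counting oracle on random matrices to 1e-12.

`size_ablation()` re-runs resize → fresh train → evaluate per input size.
The default sweep stops at 224 × 224: at the native 1000 × 600 the conv
stack flattens to 125·75·128 = 1.2 × 10⁶ features, so the first dense
layer alone holds ~3 × 10⁸ weights — supported, but not a sensible
default on a desk machine. Because single CNN runs on small cohorts are
noisy, ablation rows may average over a seed list (default 3); the
per-row `error` field records sizes too small for three poolings without
aborting the sweep.

## Problem sizes used by the tests and acceptance script

The package's own verification runs are sized for a single CPU: cohort
bookkeeping uses the full 30 × 50 design scanned at 100 A-lines × 80
depth rows (the counts are resolution-independent); the
parameter-recovery runs use 14 chicks × 8 frames (keep 6) scanned at 200
A-lines, trained at 75 × 64 for ≤50 epochs with patience 10 (clean
cohort: speckle 0.04, default cones) and ≤15 epochs (control cohort:
speckle 0.85, 20–50 µm cones at layer-level amplitude). The clean run
must reach ≥90 % chick-level test accuracy; the control must fall toward
chance, demonstrating the classifier reads anatomy rather than leaked
per-chick texture.

## What passing tests do and do not show

The generator emulates the *structure* of the study — cohort sizes,
per-chick correlation, the cone-count dichotomy, speckle, attenuation,
occluded frames — not the full difficulty of real cloacal OCT: no probe
pressure or motion artifacts, no feather/debris occlusion partway, no
inter-breed anatomical variation, i.i.d. rather than correlated speckle,
and cone geometry from configurable uniform ranges rather than measured
anatomy. Accuracy on clean phantoms is therefore an upper bound that
validates the pipeline's correctness (signal in ⇒ signal recovered;
signal destroyed ⇒ chance), not a prediction of field performance. The
reported real-world headline numbers live on a private dataset and are
out of reach by construction; nothing in this package claims to reproduce
them.

## Known limitations

* The OCT model omits sensitivity roll-off, dispersion mismatch and
  spectrometer resampling; resolution and SNR are therefore mildly
  optimistic.
* Speckle is uncorrelated between pixels.
* Training is single-threaded CPU; the 1000 × 600 native-size network is
  impractical to train here, and the ablation default excludes it.
* Whether contrast normalization was applied per image or per session in
  the original workflow is unknown; the package exposes it per image as
  an `enhance_image()`/augmentation option and leaves it off by default
  in the scanner itself.
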