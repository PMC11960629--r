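# octsex

Sexing day-old chicks from spectral-domain OCT B-scans of the cloaca, as
simulation-backed, fully tested code.

Commercial hatcheries sex chicks by manual vent inspection, which requires
rare expertise. The cloacal anatomy that experts read is subtle but
well-defined: males carry a phallus with **three** small cones, females only
**two**. Spectral-domain optical coherence tomography (SD-OCT) resolves
these structures at micrometre scale, and a compact convolutional network
can classify the resulting cross-sectional images. `octsex` implements that
entire measurement-and-classification chain for researchers in biomedical
imaging and precision livestock who want to study the approach without
access to an OCT rig or animals: a parametric tissue-phantom generator
stands in for the chicks, a physical forward model stands in for the
scanner, and everything downstream — image preparation, the classifier,
and the evaluation surface — is the same code one would run on real scans
(8-bit grayscale PNGs plus a CSV manifest).

## What is modelled

**Image formation.** A broadband source (centre wavelength λ₀ = 840 nm,
Gaussian FWHM bandwidth Δλ = 31 nm) illuminates a Michelson interferometer.
For a depth reflectivity profile r(z), the detected spectral intensity at
wavenumber k is

    I(k) = S(k) · | 1 + a·Σ_z r(z)·exp(2ikz) |²

with S(k) the source envelope and a the sample-arm coupling. Each A-line is
reconstructed as the envelope (magnitude) of the Fourier transform of the
background-subtracted spectrum; a galvo sweep of 1000 A-lines over a 4 mm
field (4 µm/px) builds the B-scan, which is cropped to its top 600 tissue
rows, normalized by its maximum envelope amplitude, and log-compressed
(−50 dB floor) into 8 bits. The axial resolution implied by the source,
(2 ln2/π)·λ₀²/Δλ ≈ 10 µm, is verified by a simulated point-spread function.

**Cohort design.** 30 chicks (15 male / 15 female), 50 frames captured per
chick, 40 retained by a quality score (mean gradient magnitude in the
tissue band), giving 1200 images that split 80/20 into 960 train / 240
test. Splits are image-stratified or — the leakage-safe default —
chick-level, so no chick contributes frames to both sides.

**Classifier.** Grayscale input resized (area averaging) to 75 × 64 px,
then three conv(3×3, "same", ReLU) + maxpool(2×2) blocks with 32/64/128
filters (75×64 → 37×32 → 18×16 → 9×8, flatten 9·8·128 = 9216), 25 %
dropout, a 256-unit ReLU layer, 50 % dropout, and a 2-way softmax, trained
with Adam (lr 10⁻⁴, batch 128, ≤1000 epochs, early stopping with patience
50 on a held-out validation fraction). Conv/pool/backprop/Adam are
implemented in the package (RcppArmadillo); no external deep-learning
framework is used. At prediction time a confidence threshold τ (default
0.6) maps low-confidence frames to a third `not_detect` outcome, and
evaluation reports the 3×3 confusion matrix with per-class, macro and
support-weighted precision/recall/F1 plus accuracy, learning curves, and
an image-size ablation.

## Worked example

Simulate a small clean cohort, train, and evaluate (about a minute on one
CPU):

```r
library(octsex)
run <- run_pipeline(
  spec = cohort_spec(n_chicks = 10, frames_per_chick = 8, keep_per_chick = 6,
                     ambiguous_rate = 0, seed = 5),
  params = phantom_params(speckle_scale = 0.05),
  train_cfg = train_config(learning_rate = 3e-4, batch_size = 32,
                           max_epochs = 25, patience = 10,
                           val_fraction = 0.15, seed = 2),
  seed = 11)
print(run)
summary(run$model)
```

```
pipeline run: 60 frames (48 train / 12 test), accuracy 1.000
confusion matrix (rows = truth, columns = predicted)
            predicted
truth        female male not_detect
  female          6    0          0
  male            0    6          0
  not_detect      0    0          0
Compact CNN for OCT chick sexing
  input: 75 x 64 grayscale (width x height)
  conv1 3x3 'same' + ReLU + maxpool 2x2 -> 37 x 32 x 32
  conv2 3x3 'same' + ReLU + maxpool 2x2 -> 18 x 16 x 64
  conv3 3x3 'same' + ReLU + maxpool 2x2 -> 9 x 8 x 128
  flatten -> 9216; dense 256 + ReLU; softmax 2
  parameters: 2,452,738
  epochs run: 25 (best 25); final val acc 1.000
```

The 10-chick cohort is scanned at reduced resolution (200 A-lines), the
frames are quality-selected 6-of-8 per chick, split chick-wise 80/20, and
the CNN separates the 3-cone males from 2-cone females perfectly — the
cone count is exactly the signal the phantoms encode. The all-zero
`not_detect` row/column appears because this cohort contains no occluded
frames and every prediction clears τ. Physics side:

```r
ar <- axial_resolution()
#> axial PSF FWHM: 10.06 um (theory 10.04 um)
```

`plot(run$model)` draws the accuracy/loss learning curves;
`run_pipeline(..., out_dir = "out")` writes PNGs, `manifest.csv`, metrics
JSON/CSV, `history.csv` and a `run_record.json` with the full
configuration snapshot. A thin CLI over the same functions lives at
`inst/cli/octsex.R` (`simulate`, `run-all`, `ablate` subcommands).

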