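---
title: "Calibration transfer for NIR spectra by unsupervised domain adaptation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration transfer for NIR spectra by unsupervised domain adaptation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirshift)
```

## The problem

A near-infrared (NIR) calibration model maps a spectrum to a reference value
— here, the tensile strength of solid wood specimens. The model is expensive
to build, because every training label comes from a destructive mechanical
test. When the spectrometer is replaced (say, a 512-channel research unit
giving way to a 118-channel OEM module on the same 900–1700 nm range), the
raw spectra change in resolution, gain, offset, baseline and wavelength
registration, and the old model no longer applies. Calibration transfer (CT)
is the family of techniques that adapt the existing model to the new
instrument without redoing the reference chemistry.

`nirshift` implements two families side by side:

* **classical standardization** — direct standardization (DS), piecewise
  direct standardization (PDS) and spectral space transformation (SST),
  which fit a linear map from the slave instrument's spectral space to the
  master's using *transfer standards*: the same physical samples measured on
  both instruments; and
* **unsupervised domain adaptation (DA) networks** — five dense-network
  models (DAN, CDAN, MDD, ETD, GLOT) that need labelled spectra only on the
  master ("source") instrument plus *unlabelled* spectra from the slave
  ("target") instrument. No paired measurements and no target labels are
  required.

## The backbone

All five networks share one architecture, deliberately built from fully
connected layers only. For NIR spectra each wavelength channel carries a
near-linear mixture of component signals, so convolution — designed to
extract local shape features from images — only entangles the
channel-to-functional-group correspondence, and pooling discards channels
that are individually informative. The backbone is therefore

* an instrument-**private** input layer per domain (`n_channels` → 64,
  ReLU), sized to each instrument's channel count;
* a **shared** hidden layer (64 → 32, ReLU), the representation on which
  all transfer losses act;
* dropout (rate 0.2) after each hidden layer, taking over the
  regularization role a pooling layer would otherwise play;
* a one-unit **sigmoid head**. Labels are scaled affinely from their
  observed range onto [0.05, 0.95] — the margin keeps targets away from the
  saturated tails — and predictions are unscaled back.

Layer widths are a free choice; 64/32 keeps
desk-scale CPU training honest and is configurable through
`adapt_config()`. Weights use seeded Glorot-style uniform initialization.
Optimizer settings follow common practice for this model family: Adam
(learning rate 0.001, momentum
0.9, weight decay 0.01) by default, RMSProp (momentum 0.9) selectable, and
a transfer-loss weight of $\lambda = 0.1$ in the joint objective.

## The five transfer losses

Writing $g$ for the shared-layer features and $f \in (0,1)$ for the head
output:

* **DAN / MK-MMD.** The squared maximum mean discrepancy between source and
  target feature batches, a biased V-statistic averaged over five Gaussian
  kernels at the median-heuristic bandwidth times $\{0.25, 0.5, 1, 2, 4\}$.
  Zero iff the feature distributions agree (in the RKHS sense); always
  non-negative.
* **Weighted CDAN.** A discriminator $D$ on the joint conditioning
  $[g f,\; g(1-f)]$ descends
  $E' = -\mathbb{E}_s[w \log D] - \mathbb{E}_t[w \log(1-D)]$.
  The weights $w$ come from a histogram of the source labels: the label
  range $[R_n, R_m]$ is split into $N = 10$ uniform segments, each segment
  gets probability $p_k = n_k / n$, and a sample whose (predicted or known)
  label falls in segment $k$ receives
  $w = (p_k - p_{\min})/(p_{\max} - p_{\min})$ — samples from well-populated
  label regions, where the spectrum–label relationship is well determined,
  drive the adversarial alignment; the sparsest segment is silenced
  (an optional floor `w_min` relaxes this; a perfectly uniform histogram
  carries no information and yields $w \equiv 1$). Source samples are
  weighted by their true labels, target samples by the model's current
  predictions mapped back to the label scale. Regression has no class
  posterior, so the two-bin soft assignment $(f, 1-f)$ plays the role the
  classifier simplex plays in classification, and the task loss is MSE
  rather than cross-entropy.
* **MDD.** An auxiliary head $f'$ on the same features maximizes the margin
  disparity $\;\mathrm{mean}_t[(f'-f)^2] - \gamma\,\mathrm{mean}_s[(f'-f)^2]$
  (margin $\gamma = 4$); the main network minimizes source MSE plus
  $\eta = 1$ times it. Squared differences replace the margin cross-entropy
  terms, which have no regression analogue.
* **ETD.** Entropic optimal transport between the domains with pair cost
  $\|g_i^s - g_j^t\|^2 + (f_i^s - f_j^t)^2$, reweighted multiplicatively by
  an attention network (two dense layers, softplus output, scores
  normalized to mean 1) and solved by log-domain Sinkhorn iterations. A
  Kantorovich potential network is fitted as a critic to the OT dual
  $\mathrm{mean}_s[g(x)] - \mathrm{mean}_t[g^c(y)]$ with the hard
  c-transform $g^c(y) = \max_i(g(x_i) - c(x_i, y))$; its dual value is a
  lower bound on the primal cost (weak duality) and serves as a diagnostic.
* **GLOT.** A global–local regularizer: the global term is the entropic OT
  distance between the feature clouds; the local term pushes each source
  feature a distance `local_radius` along the head's input gradient and
  penalizes the squared prediction change — a one-step surrogate for
  worst-case robustness within an $L_2$ ball. For a linear head with weight
  vector $w$ the local term equals $(\mathrm{radius}\cdot\|w\|)^2$ exactly,
  which the tests exploit as a closed-form oracle.

## Training protocol and its stabilizations

Training runs in three seeded stages (`nir_adapt()`):

* **A — supervised warm-up** (default 2000 iterations): private-source +
  shared + head on source MSE. For MDD the auxiliary head is pretrained in
  parallel to predict the source labels, so at the start of adaptation it
  agrees with the main head on the source manifold and is free only off it.
* **B — private adaptation** (default 1000): the target-private layer is
  initialized by resampling the *trained* source-private weights onto the
  target grid (linear interpolation per hidden unit, rescaled by the
  channel-spacing ratio), then the first half of the stage descends the
  transfer loss updating **only** the target-private layer, and the second
  half refreshes private-source + shared + head on source MSE.
* **C — joint fine-tune** (default 2000): total loss
  $\mathrm{MSE}_s + \lambda\,L_{\text{transfer}}$ over all blocks, with the
  inner players (discriminator, margin adversary, attention, potential)
  updated by their own min–max rules and a 0→1 coefficient ramp on the
  adversarial feature gradients.

Several design choices here were forced by observed optimization behaviour
and are part of the package's method, not incidental details:

* **Stage B moves only the target-private layer.** Letting the shared trunk
  follow a label-free objective collapses the features (a zero feature
  vector minimizes every alignment loss trivially); anchoring the trunk
  turns stage B into alignment of the new instrument's routing against a
  fixed, task-bearing representation.
* **Non-saturating adversarial gradients (CDAN).** Literal gradient
  reversal of $E'$ gives the feature player a gradient that vanishes
  exactly when the discriminator is winning; under Adam's per-parameter
  normalization the resulting noise is amplified into a destructive random
  walk. The feature player instead descends $-\mathbb{E}_t[w\log D]$ /
  $-\mathbb{E}_s[w\log(1-D)]$ — the standard non-saturating form — and the
  prediction enters the discriminator as conditioning only.
* **Damped transfer-driven steps.** Blocks whose only gradient source is
  the transfer objective (the target-private layer; all of stage C's
  fine-tuning) step at `transfer_lr_factor` (default 0.1) times the base
  rate, and purely adversarial updates carry no weight decay — decaying an
  adversary or an aligned private layer toward zero manufactures spurious
  disagreement. Stage C at the damped rate refines rather than undoes the
  stage-B alignment.
* **MDD specifics.** The disparity is evaluated full-batch with three inner
  ascent steps per feature step (a minibatch adversary overfits 32 samples
  and turns the pursuit into noise), and the adversary has a hidden layer —
  a linear-in-features adversary cannot punish collapsed target features,
  which are otherwise a degenerate disparity minimizer.
* **OT routing and batch.** For both transport losses (ETD, GLOT) the
  fitted source geometry is the reference frame: the plan gradient moves
  only the target side, since plan-mismatch pulls on the source features
  measurably corrupt the label map. ETD additionally transports a larger
  batch than the task uses (`ot_batch`, default 64): a 32-point cloud is
  not representative enough of the source geometry for the transport plan
  to be meaningful, and the resulting noise grows with the diversity of the
  source data.

With $\lambda = 0$ stage C degenerates to pure source fitting and the
target-private layer is bit-identical to its post-stage-B state — a
property the tests assert.

## The synthetic two-spectrometer benchmark

Because real two-spectrometer wood datasets are not freely bundled, the
package
ships a generator (`generate_paired()`) that emulates the measurement
process end to end:

* **Chemistry.** Three absorbing components ("cellulose-like",
  "lignin-like", "hemicellulose-like") with 2–3 Gaussian bands each between
  950 and 1650 nm; concentrations uniform on $[0.1, 1]$; the label is a
  fixed linear functional of the concentrations
  (coefficients $(70, 35, -20)$, giving a ≈30–120 span) plus Gaussian noise
  with sd 4 — destructive tensile testing has a coefficient of variation
  around 5–10%, and this noise sets the accuracy ceiling (R ≈ 96%) any
  model can reach.
* **Band-shape variability.** Every physical sample shifts all its bands by
  a common $N(0, 1.5\,\mathrm{nm})$ draw and scales their widths by
  $1 + N(0, 0.03)$ — the hydrogen-bonding/temperature effects that move NIR
  overtone bands between specimens. This is the feature that gives real
  spectra an intrinsic dimensionality far above the component count; without
  it a handful of transfer standards reconstructs the instrument map
  exactly and the benchmark cannot discriminate between methods.
* **Instruments.** Spectra are evaluated on a dense 2048-point reference
  grid (880–1720 nm), convolved with each instrument's Gaussian response,
  shifted, distorted by gain/offset/baseline, sampled to the instrument
  grid, and degraded with noise. The default master mirrors a 512-channel,
  1.56 nm-FWHM unit (noise 0.01 AU); the default slave a 118-channel,
  6.83 nm unit with gain 1.25, offset 0.04 AU, baseline slope
  2×10⁻⁵ AU/nm, 2 nm wavelength shift and noise 0.015 AU. Each *scan*
  additionally draws small gain/offset/slope deviations
  (repeatability jitter), as real instruments do between measurements.
* **Pairing.** The first `min(n_source, n_target)` samples share
  concentration and band-shape draws across instruments, so they can serve
  as physically paired transfer standards for DS/PDS/SST; the networks
  never use the pairing.

What the generator does *not* emulate: real wood optical constants,
scatter/particle-size artifacts of diffuse reflectance (SNV/MSC territory),
detector nonlinearity, and any non-Gaussian band shapes. Passing the
benchmark therefore shows that the methods recover a known, structured
instrument shift under realistic noise — not that they meet any particular
accuracy on real wood.

## Evaluation designs

`r_squared_percent()`, `rmse()`, `rmsep()` and `rmsecv()` (k = 10 seeded
folds, models refit from scratch per fold) are the metrics.
`split_ratio_sweep()` reruns each network over training fractions
25–70% in 5% steps with fresh splits per repetition;
`transfer_sample_sweep()` refits each classical map on 30/50/70% of the
paired standards, corrects the slave spectra, and scores them with one
fixed ridge model trained on the master data — the scorer is held constant
so the comparison isolates the transfer map. The sweep averages over
seeded standard-selection shuffles (the reported cells are mean ± sd), and
DS selects its ridge penalty by generalized cross-validation: with noisy
standards an under-regularized DS map develops the classic variance peak
where the standard count approaches the slave channel count.

The package's own benchmark (exercised by the test suite and
`scripts/acceptance.R`) uses realistic campaign sizes — 196 labelled master
spectra, 270 unlabelled slave spectra — with reduced iteration budgets
(400/400/400 rather than the 2000/1000/2000 defaults) and a handful of
training seeds (five in the test suite, three in the reproduction script);
these sizes keep a full run in single-digit minutes on one CPU core while
leaving the qualitative conclusions unchanged. The unadapted baseline for
each method is the controlled comparison: same seed, same initialization,
warm-up only. On this benchmark all five networks improve target-domain R
over their baselines (median gains on the order of 10–30 points), and
classical accuracy rises with the transfer-standard fraction, with the
networks' headroom above DS/PDS/SST concentrated where standards are few —
the qualitative pattern reported for real wood data in the
calibration-transfer literature.

## Numerical notes and limitations

* Sinkhorn iterations run in the log domain, and the returned plan is
  rounded onto the transport polytope (row/column downscaling plus a
  rank-one deficit repair), so its marginals are exact at any
  regularization strength. Training uses ε = 0.05 and 100 iterations per
  evaluation — enough that the rounding correction is negligible; the
  acceptance checks use ε = 0.015 and 5000 iterations, where 5×5 plans sit
  within 5% of the exact linear-program optimum.
* Transport and attention factors are held fixed when differentiating the
  OT losses (the standard envelope approximation); the residual against
  full finite differences is a few percent and does not affect descent.
* The c-transform in the potential dual uses the hard max; ties break to
  the first index.
* Histogram segments are half-open with the last segment closed; values
  outside the range clamp to the end segments; a uniform histogram yields
  weight 1 everywhere (the 0/0 case carries no information).
* `random_split()` assigns `floor(ratio·n)` samples to the training set.
* All randomness flows from a single seed through `derive_seed(seed, tag)`
  (a fixed integer hash), so every run, sweep cell and fold is bit
  reproducible; `config_echo.yaml` in every output directory allows exact
  re-execution.
* Known limitations: the adversarial methods remain the most
  seed-sensitive (single negative-gain seeds occur); MDD's margin signal is
  weak once domains are roughly aligned; and the dense backbone is not
  meant for spectra longer than a few thousand channels.
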