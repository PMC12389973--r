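---
title: "Methods: cortical-source EEG depression classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cortical-source EEG depression classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `corticlass`, the
parameters that matter, what the synthetic generator does and does not
emulate, and the numerical and design choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The model

## Forward and inverse problem

Scalp EEG is modelled as `Φ = K J + ε`, with `K` the `L × S` lead field
(electrodes × cortical sources), `J` the source current time courses
and `ε` sensor noise. Because `S ≫ L` the inverse problem is ill-posed;
we use the Tikhonov-regularized minimum-norm estimate

    Ĵ = argmin_J ‖Φ − KJ‖²_F + α‖J‖²_F = Kᵀ (K Kᵀ + αI)⁻¹ Φ

with `α = 0.05` by default. The raw minimum-norm solution is biased
towards superficial/high-gain sources, so each source estimate is
standardized by its model-implied standard deviation (sLORETA):
with fixed scalar orientations, `J_std[i, t] = Ĵ[i, t] / √v_i` where
`v_i = [Kᵀ (K Kᵀ + αI)⁻¹ K]_{ii}` is the i-th diagonal of the
resolution matrix. Two choices are worth flagging:

* **Model covariance.** The standardization covariance is taken as
  `C = K Kᵀ + αI` (signal + regularization), the convention under which
  the standardized estimate has *zero localization error* for a single
  noiseless source — the property that motivates the method and that
  the test suite verifies by brute force over all candidate sources.
* **Orientation.** Sources have a fixed scalar orientation
  (normal-to-surface convention), so the general matrix-valued
  standardization reduces to division by `√v_i`.

Source series are averaged (signed mean; an absolute-value mean is
available via `rectify = TRUE`) within each atlas region. With 68
regions the labels default to the Desikan–Killiany parcel names
(`-lh`/`-rh` suffixed); any other count gets generic labels. α is fixed
rather than estimated by generalized cross-validation: the pipeline's
downstream consumers (band features) are insensitive to the small α
range GCV would explore, and a fixed value keeps epochs comparable.

## Preprocessing

Fixed order: notch → band-pass (4–80 Hz) → downsample → z-score →
epoching (2 s, at most 150 per recording) → amplitude artifact flag.
Choices:

* **Filter family.** Zero-phase forward–backward Butterworth order 4
  (the notch uses an order-2 prototype, i.e. an order-4 band-stop with
  a ±2 Hz stop band). Zero-phase matters because phase-locking values
  downstream must not inherit filter phase lag. Filters are designed by
  the classical analog-prototype + bilinear transform route and applied
  with odd-extension padding and steady-state initial conditions
  (validated against reference implementations to machine precision
  during development). A pure tone at the line frequency retains a
  small edge-ringing residual after zero-phase notching — this is
  intrinsic to IIR notching of finite signals, not a defect; the
  attenuation contract (≥ 20 dB at the line frequency, < 10% residual
  RMS at the recording rate) is enforced in the tests.
* **z-score scope.** The normalization formula is per signal; we apply
  it per channel over time with the population (divide-by-T) standard
  deviation, before epoching so that epoch statistics remain
  comparable across the recording. A constant channel is an error
  (`zero-variance-channel`).
* **Downsampling** only by integer factors (anti-alias low-pass at 80%
  of the target Nyquist, then decimation); non-integer ratios are
  rejected rather than resampled, to avoid interpolation dialects.
* **Epochs** are non-overlapping from t = 0 (150 × 2 s epochs from a
  ≥ 300 s recording implies no overlap); a trailing partial window is
  dropped.
* **Artifacts.** A simple amplitude threshold (default 10 SD after
  z-scoring) flags epochs; automated artifact *removal* pipelines are
  out of scope. The 50 Hz notch sits inside the 30–80 Hz gamma band, so
  gamma features have a spectral hole; this mirrors the preprocessing
  that the pipeline reproduces and is deliberately left as-is.

## Features

Per band (theta 4–8, alpha 8–13, beta 13–30, gamma 30–80 Hz — the
beta/gamma boundary is made contiguous at 30 Hz to avoid a 1 Hz dead
zone) and per ROI, eight features in fixed column order: clustering
coefficient, local efficiency, peak, skewness, band power, relative
power, sample entropy, fuzzy entropy; `D = 4 × 8 = 32`.

* **PLV**: `|mean_t exp(i(φ_p − φ_q))|` with instantaneous phases from
  the analytic (Hilbert) signal of the band-passed series. Bounded in
  [0, 1], symmetric, amplitude-invariant.
* **Graph metrics** need a binary graph; the binarization threshold is
  not fixed by any principle, so the default is the PLV midpoint 0.5,
  configurable (`plv_threshold`). Nodes with degree < 2 take clustering
  and local efficiency 0 (the defining ratios vanish). Shortest paths
  for local efficiency are computed inside the subgraph induced by a
  node's neighbours; disconnected pairs contribute 0 (1/∞).
* **Spectral**: Welch PSD with 1 s Hann windows, 50% overlap (a 2 s
  epoch gives three windows); band power integrates over `[low, high)`,
  relative power normalizes by total 4–80 Hz power so the four bands
  partition to 1 on band-limited input. Peak is `max |x|` (a zero-mean
  signal makes the signed maximum sign-arbitrary); skewness uses
  population moments.
* **Entropies**: template length `m = 2` and tolerance `r = 0.2 × SD`
  (the universal defaults in this literature); Chebyshev distance,
  self-matches excluded, the same `T − m` templates for both lengths.
  Fuzzy entropy removes each template's mean and replaces the hard
  tolerance with the smooth membership `exp(−(d/r)²)`. Both are
  verified against naive O(T²) double-loop oracles.

Features are computed **per epoch** (not per subject-average): the
sample unit downstream is the epoch, which matches the epoch-level
sample accounting the pipeline is designed around.

## Network

Input is the `N × 32` feature matrix. The attention stack has 4 layers;
each layer runs `H = 4` heads (`d_h = D/H` when divisible, else
`d_h = D` with the output projection restoring `D`), concatenates,
projects, adds the residual and applies ReLU. No layer normalization:
the residual + ReLU recipe is implemented exactly as specified, with
the variant left to a future flag. The per-epoch graph is the Pearson
correlation of the broadband ROI series thresholded at `φ = 0.3`; the
diagonal is forced to 0 before the normalization `D^{-1/2}(A+I)D^{-1/2}`
adds a single self-loop (self-correlation is trivially 1, and keeping
it would double the self-loop). Spectral radius of `Â` is ≤ 1 by
construction (tested on random graphs). Two GCN layers
(`32 → hidden → hidden`, hidden = 512 by default) are followed by mean
pooling over nodes and a linear 2-class head; the domain discriminator
is a 2-layer perceptron (hidden → 256 → K) behind the gradient
reversal layer, with one domain per training subject. Dropout (0.3)
acts on the first GCN layer's output during training only.

## Losses and training

The feature extractor minimizes
`L = L_focal + γ_c·L_center − λ·L_adv`; the discriminator minimizes
`L_adv`. Both are realized in one backward pass through the gradient
reversal layer (forward identity, backward ×(−λ)); the suite checks
that one optimizer step with the GRL equals the explicit two-term
update, and that all gradients match finite differences.

* **Focal loss**: `−Σ β_τ (1−p_τ)^γ log p_τ`, `γ = 2`; `β` defaults to
  inverse class frequency normalized to mean 1 (the loss itself is
  written as a sum over samples; the implementation averages over the
  batch for scale stability, with `reduction = "sum"` available — at
  batch size 1 the two coincide). Probabilities are clamped at 1e-12
  with a warning.
* **Adversarial loss**: K-domain cross-entropy; λ defaults to 0.1 and
  is ramped from 0 with the standard sigmoid schedule
  `2/(1+exp(−10p)) − 1` over training progress `p` (ramping avoids the
  adversary destabilizing early training; disable with
  `lambda_ramp = FALSE`).
* **Center loss**: squared distance to class centers (`γ_c = 0.01`);
  centers are updated by exponential moving average (momentum 0.9) of
  batch class means — stable with batch size 16 where per-batch class
  counts fluctuate.
* **Optimizer**: Adam at 5e-5, batch 16, up to 70 epochs, early
  stopping patience 15 on validation accuracy — the reference
  hyper-parameters. Splits are subject-wise stratified 70/15/15 so no
  subject's epochs leak across partitions; with exactly two subjects in
  a class the validation subject doubles as the test subject (with a
  warning). Depressed (label 0) is the positive class in all metrics;
  precision/recall hit by 0/0 are reported as 0 and flagged.

# Synthetic data: what it emulates, what it does not

The generator emulates the *structure* of the clinical cohort the
pipeline targets: per-subject resting recordings (default 46 DP vs 74
HC subjects, 64 channels, 500 Hz, 300 s → 150 two-second epochs),
class imbalance, and subject-level distribution shift. Its parts:

* **Lead field**: a Gaussian matrix with orthonormalized then
  perturbed rows — full row rank, condition number of `K Kᵀ` bounded by
  1e6, sources assigned to ROIs in contiguous blocks. It is *not* a
  boundary-element head model; the inverse mathematics is agnostic to
  how `K` arose, and head-model computation is out of scope. `L ≤ S`
  is required.
* **Sources**: band-limited (4–80 Hz) Gaussian noise per source;
  depressed subjects additionally receive a 6 Hz (theta) oscillation
  with a slow sinusoidal envelope in the sources of a designated
  affected-ROI set (default the first 2 ROIs), scaled by
  `class_effect`. Theta is chosen because low-frequency abnormalities
  are the best-replicated spectral finding in this clinical
  population, and a band-confined effect exercises the band-resolved
  feature machinery.
* **Shift and noise**: a per-subject multiplicative gain
  `1 + N(0, domain_shift_sd)` on the sources models inter-subject
  amplitude variability; sensor noise is i.i.d. Gaussian
  (`noise_sd`). With `noise_sd = 0` the scalp data equals `K J`
  exactly (tested).

No public amplitude scale exists for the injected signals, so the
scales are arbitrary and documented rather than calibrated: a green
end-to-end test establishes that the pipeline recovers a *strong,
band-confined, spatially localized* class difference across subjects
under shift and noise — not that it would reach any particular accuracy
on real recordings, whose artifacts (ocular, muscular), non-Gaussian
spectra, and subtler effect sizes the generator does not emulate.

# Scaling of the test suite

The reference configuration (64 channels, 15k sources, 512 hidden
units, 150 epochs/subject) is far beyond desk-scale CI. Tests shrink
sizes, not mechanisms: 8–40 sources, 4–8 ROIs, 6–16 channels, hidden
16–24, 2 attention layers, 8 epochs/subject, learning rate raised to
2e-3 so small models converge within tens of epochs. The end-to-end
acceptance check trains on 20 synthetic subjects (3 seeds) and requires
mean held-out subject-wise accuracy ≥ 95%.

# Numerical choices

* Probability clamp 1e-12 before logs; softmax computed with max
  subtraction.
* Glorot-uniform initialization, zero biases; all randomness (init,
  splits, shuffling, dropout) derives from one seed — two runs with the
  same seed produce bit-identical loss histories.
* `stats::dist(method = "maximum")` performs the entropy template
  sweeps in C; `filtfilt` padding follows the standard
  `3 × max(len(a), len(b))` convention (longer odd extensions
  *increase* tone edge-ringing).
* Degenerate inputs error loudly: zero-variance channels, constant
  series in correlation, zero total power, single-class datasets,
  recordings shorter than one epoch.

# Interfaces

File interchange is plain text: per-subject TSV matrices + CSV
manifest for recordings, TSV + CSV for lead fields, CSV per epoch for
feature matrices and adjacencies. EDF and binary array formats are not
supported (no reader/writer dependency is available in the supported
stack); the CSV/TSV route keeps every artifact inspectable. The CLI
(`corticlass simulate|features|train|ablate`) drives the same code
paths as the R API. Training history is written as CSV rather than
JSON-lines — same fields, one row per epoch.

# Ablations

`ablation_run()` executes the 8 on/off configurations S1–S8 of (CFE,
FA, FADA) with shared seeds: CFE-off computes the identical feature set
on scalp channels instead of reconstructed ROI series; FA-off bypasses
the attention stack; FADA-off trains with plain cross-entropy (γ = 0,
uniform β, λ = 0, γ_c = 0). S8 reproduces the main pipeline exactly for
the same seed (tested).

# Known limitations

* The adversary assumes one domain per training subject; unseen test
  subjects are aligned only implicitly.
* The GCN depth (2) and the classifier/discriminator heads are minimal
  standard choices; the reference architecture does not pin them down.
* Entropy features dominate runtime (O(T²) per series even in C);
  epochs much longer than 2 s at high rates get expensive.
* The synthetic generator's effect model is a single oscillatory
  mechanism; it cannot probe features the effect does not touch (e.g.
  skewness separates classes only through filtering artifacts).
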