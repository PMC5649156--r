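---
title: "Blink-related oscillation analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blink-related oscillation analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, what the
synthetic data generator does and does not emulate, and the choices made
where the design was genuinely open. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## The phenomenon and the measurement model

Each spontaneous blink is followed, in resting MEG, by a transient
delta-band (0.5–4 Hz) cortical response peaking ~250 ms after full eyelid
closure (T0), localizing to medial posterior parietal cortex. Measuring it
requires separating three superimposed signals: the ocular artifact (the
eyelid/eyeball current dipole, orders of magnitude stronger than cortex at
frontal sensors), ongoing background rhythms, and the blink-locked
response itself. The pipeline's logic is therefore: detect blinks on the
vEOG; remove the ocular field by ICA; and demonstrate the residual
blink-locked response at the sensor level (GFP, time-frequency) and source
level (minimum-norm contrasts, virtual electrodes) against a *control*
condition cut from the same data with pseudo-random timing — identical
noise and ongoing activity, no blink locking.

## Forward model

MEG outside a spherically symmetric conductor depends only on the
primary-current dipole and not on the conductivity profile, and radial
dipoles are silent; the closed-form (Sarvas) field is therefore an
appropriate and exactly testable forward model when no individual anatomy
exists. Axial gradiometers are modeled as the difference of the radial
field at two coils 5 cm apart along the sensor radius (two-point
difference, not integrated coil areas). Sources live on a spherical shell
(radius 70 mm inside a 90 mm conductor) with two tangential orientations
per point; the two precuneus-proxy locations are the nominal coordinates
(−8, −68, 49) and (7, −68, 39) mm scaled radially onto the shell. Grid
spacing defaults to 10 mm; the shell resolution is a free parameter
because no mesh is prescribed by the underlying study design.

Channel regions (frontal / central / parietal / temporal / occipital) are
fixed angular sectors: below 50° elevation, the anterior 60° sector is
frontal, the posterior 60° occipital, and the lateral bands temporal;
above 50°, anterior half central, posterior half parietal. Any sectoring
consistent with "grouping by location" would do; this one is deterministic
and keeps all five groups non-empty for realistic channel counts.

## Synthetic data generator

The generator is first-class, tested code. Its defaults are the target
acquisition: 151 axial gradiometers (5 cm baseline) at 1200 Hz for 600 s;
blinks as a homogeneous Poisson process at 11.3/min thinned to a 3 s
refractory gap; vEOG morphology M1–M4 = (43.70 µV, 0.329 s, −10.07 µV,
0.399 s) as a Hann-lobe biphasic template; and a blink-locked delta
response at both precuneus proxies peaking 250 ms after T0.

Components, each drawn from a numbered substream of one master seed
(blink times; per-blink amplitudes; vEOG noise; background sources; alpha
rhythm; sensor noise; array jitter; ICA init; per-subject parameters):

- **Background**: 30 grid dipoles with 1/f-power time courses plus a
  posterior 10 Hz rhythm, scaled to 120 fT and 60 fT mean per-channel RMS,
  plus 60 fT white sensor noise (≈7 fT/√Hz over the 0.5–45 Hz band,
  typical instrument noise).
- **Ocular artifact**: one equivalent dipole at (0, 75, −25) mm —
  anterior-inferior, outside the source grid but inside the conductor —
  whose moment follows the clean vEOG train at 3 nA·m/µV, giving ~2 pT
  peak fields at frontal sensors and the strongly frontal topography that
  artifact removal must eliminate.
- **Neural response**: a Hann-windowed one-cycle wave — positive lobe
  (0.4 s base width, amplitude 1) peaking at the 250 ms latency, negative
  lobe (0.5 s, amplitude −0.8) troughing at 700 ms. The lobe areas cancel,
  so the pulse has no DC component and concentrates its power in the delta
  band (~91%; a strictly higher in-band fraction is impossible for any
  zero-integral biphasic pulse with this peak/trough geometry, because the
  first moment of the waveform fixes a sub-0.5 Hz floor, and band-limiting
  it by filtering would smear deterministic ringing across the whole
  epoch). Peak moment: 8 nA·m per proxy point.
- **Between-subject variability**: per-subject morphology parameters drawn
  with across-subject SDs (3.10 µV, 0.016 s, 1.13 µV, 0.017 s), a
  lognormal (σ = 0.3) neural amplitude scale, and a lognormal (σ = 0.2)
  background scale. Without this, all subjects are identical up to noise,
  group t-statistics reach implausible values (~100), and sign-flip
  permutation nulls degenerate — a known pathology of permutation tests
  under near-deterministic effects.

The neural amplitude is a documented package constant, not a reported
value: it is set so that blink-locked effects *emerge* at the trial counts
a 10-minute run provides (~60 blinks), i.e. single-trial sensor SNR around
−10 dB and trial-averaged group statistics of realistic magnitude
(windowed GFP t ≈ 10–15 at n = 12, not hundreds).

What the generator does **not** emulate: saccades and cardiac fields, head
movement, sensor drift or line noise (a notch filter is provided but off
by default), anatomical variability of the head model (one shared sphere
per cohort), and between-subject variation in blink *rate*. Passing tests
therefore show the pipeline recovers planted effects under idealized
spatial structure; they do not certify performance against real artifact
diversity.

## Signal processing choices

- **Filter-then-epoch**: all band-limited quantities (delta GFP, source
  contrasts, VOI traces) are computed from epochs cut out of the
  continuously filtered recording, never by filtering 3 s segments:
  zero-phase filtering of short epochs inflates variance near the epoch
  edges (the padding is reflection, not data), which biases the pre-blink
  window — 200 ms from the edge — and makes pre-vs-post contrasts reject
  under the null.
- **Filters**: zero-phase Butterworth. Band-passes apply the squared
  magnitude response |H(f)|² (the exact transfer function of a
  forward-backward pass) in the frequency domain on odd-reflection padded
  signals: numerically stable at 0.5 Hz cutoffs even at 1200 Hz sampling,
  vectorized across channels, and exactly zero-phase. Order 4 per stage;
  the notch is a time-domain forward-backward band-stop.
- **Morlet transform**: 6-cycle complex wavelets, unit L2 norm, trimmed at
  ±2.5σ. Frequencies whose support (n_cycles/f) exceeds the 3 s epoch are
  dropped with a warning — at 6 cycles this means frequencies below 2 Hz
  cannot be estimated from single 3 s epochs, so the "delta band" of the
  spectral statistics is effectively 2–4 Hz. Coefficient power near the
  epoch edges is renormalized by the in-epoch wavelet energy so stationary
  signals keep flat expected power; without this, the pre-blink window
  (200 ms from the epoch edge) is biased low and the post-vs-pre spectral
  test rejects under the null.
- **ICA**: FastICA (tanh contrast) on PCA-whitened MEG with a seeded
  orthonormal initialization; the unmixing matrix is estimated on an
  evenly strided subsample of at most 20,000 samples (instantaneous mixing
  is time-invariant, so any time subset identifies it) and sources are
  derived on the full data. Components are canonicalized (variance order,
  positive largest mixing weight) for reproducibility. Ocular components
  are flagged by |r| ≥ 0.8 against the blink-band vEOG — an automated
  stand-in for per-subject visual inspection.
- **Minimum norm**: `M = Gᵀ(GGᵀ + λI)⁻¹`, λ defaulting to 1% of the mean
  Gram diagonal; `estimate_lambda()` implements a discrepancy-principle
  alternative that matches the residual to a baseline noise floor. No
  noise-covariance whitening (the synthetic sensors are homogeneous) and
  no depth weighting: the single-shell grid sidesteps depth bias.
- **Smoothing**: Gaussian on the shell (FWHM 8 mm), column-normalized so
  each source distributes unit mass — total image mass is preserved
  exactly.

## Statistics

- Windowed GFP contrast: post 150–350 ms (spanning the blink-condition GFP
  peak) vs pre −1300 to −1100 ms, paired t per condition.
- Spectral test: group mean post−pre delta log-power, null by
  within-subject pre/post label swaps (sign flips), one-sided for
  increases. Although the resampling is sometimes described in bootstrap
  terms in this literature, label permutation gives an exact null and is
  what is implemented.
- Source FWE: one-sample T per voxel (optionally after regressing out the
  centered blink-count covariate), null from the maximum |T| over voxels
  under subject sign flips — exhaustively enumerated when 2^n ≤ n_perm.
  Corrected p-values compare the *signed* observed T against the max-|T|
  null, so only the tested direction can reach significance.
- VOI cluster test: pointwise paired t between blink and control VOI time
  courses; contiguous same-sign suprathreshold samples form clusters
  scored by size (sample count); null from the max cluster size under
  sign flips; p-values include the observed labeling (never exactly 0).
  The cluster-forming threshold defaults to two-sided α = 0.01. The more
  common α = 0.05 was tried first and proved wrong for this regime: with a
  waveform shape shared across subjects, sign-flip replicas at ~30%
  amplitude still clear a t-threshold of 2.2 across entire lobes, so the
  null max-size distribution inherits the longest lobe's duration and
  shorter real deflections can never reach significance regardless of
  effect size. A stricter forming threshold — independently recommended in
  the cluster-inference literature — separates observed deflections
  (t ≈ 10–16) from flip replicas. Because the size statistic is
  integer-valued, the test is conservative under the null (achievable
  p-values are coarse); the calibration tests check that familywise error
  never exceeds the nominal level rather than that it attains it.
- Interpreting the VOI cluster list: the delta-band zero-phase filter's
  response to the planted pulse is deterministic and shared across
  subjects, so small shape-common deflections at the epoch margins also
  form significant clusters. These are real (planted-signal) features of
  the synthetic model, not false positives.

## Power-ratio validation of artifact removal

The blink-to-baseline power ratio is a per-subject, per-region variance
ratio at two single latencies. After successful cleanup the ERF at those
latencies is spatially correlated background noise, so the ratio is
F-like with few effective degrees of freedom (set by the number of
dominant background sources in a region, not its channel count) and
scatters widely around 1 even under a perfect null — single-subject
values outside [0.5, 2] are expected. Group-level summaries are the
meaningful quantity; the pipeline reports per-region paired t-tests
(pre vs post ICA, Bonferroni ×5) and log-domain means, and the acceptance
checks assert the group geometric mean near unity plus per-subject
*improvement* (post closer to 1 than pre).

## Problem sizes

Full-scale defaults (151 channels, 1200 Hz, 10 min) are practical but
slow; the shipped tests and the acceptance script run the same pipeline at
desk scale, chosen as the smallest sizes that preserve every analyzed
band and trial count: 12-subject cohorts, 40 channels at 100 Hz (Nyquist
well above the 45 Hz analysis edge), 480 s runs (~57 blinks each after
the 3 s exclusion, matching the ~60-trial regime the method targets),
14 mm source grids, and 300–1000 permutations per test. The blink
detector's operating point is additionally measured at 250 Hz, where the
±50 ms matching tolerance spans many samples.

## Known limitations

- The spherical conductor and shared head model ignore anatomy;
  localization statements are relative to the nominal frame only.
- Delta-band spectral estimates from 3 s epochs exclude 0.5–2 Hz (wavelet
  support), and the windowed statistics near epoch edges lean on the
  stationarity correction.
- The split-half reliability correlates *sorted* half-samples, as
  specified upstream; sorted-order correlation is high by construction
  for any spread-out sample, so it measures consistency of the value
  range rather than subject-level pairing.
- Control epochs are not purged of blinks (they are only pseudo-random
  with respect to them); a strict mode would drop control epochs
  overlapping any T0, but the trial-matched design used here mirrors the
  intended contrast.
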