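# bromeg — blink-related oscillations in MEG

Spontaneous eye blinks are followed by a transient, delta-band (0.5–4 Hz)
cortical response — a *blink-related oscillation* (BRO) — that peaks about
250 ms after full eyelid closure and localizes to medial posterior parietal
cortex (precuneus). `bromeg` implements the complete analysis chain used to
characterize this response in whole-head axial-gradiometer MEG with a
simultaneous vertical EOG (vEOG) channel, together with a physics-based
synthetic data generator that plants the effect with known ground truth, so
every stage of the chain can be validated quantitatively.

The pipeline, for a cohort of subjects:

1. **Blink detection** on the 0.1–30 Hz vEOG by sliding normalized
   cross-correlation against a biphasic blink template; candidates pass an
   amplitude threshold and a 3 s temporal exclusion (both members of any
   close pair are dropped). T0 — the blink maximum — anchors all epochs.
   Morphology features M1–M4 (positive peak amplitude/width, negative peak
   amplitude/latency) summarize each subject's average blink, and their
   across-subject consistency is scored by sorted split-half reliability
   (1000 random half-splits, mean Pearson correlation).
2. **Preprocessing**: 0.5–45 Hz zero-phase band-pass, ICA decomposition of
   the MEG channels, removal of components correlated with the vEOG
   (|r| ≥ 0.8), then 3 s epochs for a *blink* condition centered on T0 and a
   trial-matched *control* condition placed pseudo-randomly with respect to
   blinks near the middle of the run. Artifact removal is validated by the
   blink-to-baseline power ratio per scalp region,
   `ratio = Σ(y_i − ȳ)² / Σ(x_i − x̄)²`, comparing the across-channel ERF
   deviations at 0 ms versus −1000 ms, with paired t-tests (Bonferroni) and
   a repeated-measures ANOVA across regions.
3. **Sensor space**: delta-band global field power (GFP — the spatial
   standard deviation across channels per time point), paired-t contrasts
   of mean GFP in 150–350 ms versus −1300 to −1100 ms windows, and 6-cycle
   Morlet wavelet log power (0.5–6 Hz) with per-trial baseline correction
   (−1500 to −500 ms) tested by a subject-level sign-flip permutation.
4. **Source space**: Sarvas single-sphere forward model for the axial
   gradiometer array, Tikhonov-regularized minimum-norm inversion,
   delta-band post-vs-pre contrast images smoothed with an 8 mm FWHM
   kernel, group familywise-error control by max-statistic sign-flip
   permutation (with the per-subject blink count as covariate), and
   virtual-electrode time courses from 5 mm precuneus-proxy VOIs compared
   between conditions by a max-suprathreshold-cluster permutation test
   (5000 permutations by default).

## Worked example

```r
library(bromeg)

cfg <- bro_sim_config(n_chan = 40, sfreq = 100, duration = 480,
                      grid_spacing = 0.014)       # desk-scale acquisition
cohort <- simulate_cohort(12, cfg, seed = 1)
rep <- run_pipeline(cohort, analysis = bro_analysis_config(
  n_perm_fwe = 500, n_perm_cluster = 1000, n_perm_spectral = 500,
  ica_n_components = 26, ica_fit_samples = 6000, ica_maxit = 50), seed = 2)
print(rep)
```

prints (numbers from this exact call):

```
<bro_report> 12 subjects, master seed 2
  blinks: 56.8 +- 4.5 per subject (7.1 +- 0.6 per minute)
  morphology: M1 43.86 uV, M2 0.297 s, M3 -11.16 uV, M4 0.388 s (means)
  split-half reliability: 0.905, 0.931, 0.940, 0.923 (consistent: TRUE)
  GFP post vs pre [blink]: t = 15.42, p = 8.5e-09
  GFP post vs pre [control]: t = -2.03, p = 0.067
  blink GFP peak latency: 250 ms
  delta spectral permutation: blink p = 0.002, control p = 0.986
  Bpost_gt_Bpre: 78 suprathreshold voxels (precuneus proxies included: TRUE)
  Bpre_gt_Bpost: 0 suprathreshold voxels
  Cpost_gt_Cpre: 0 suprathreshold voxels
  Cpre_gt_Cpost: 0 suprathreshold voxels
  VOI left: 5 significant cluster(s) at -1250--980 ms (+), -620--90 ms (-), 80-400 ms (+), 460-870 ms (-), 920-1500 ms (+)
  VOI right: 5 significant cluster(s) at -1370--1080 ms (+), -610--100 ms (-), 100-410 ms (+), 460-870 ms (-), 910-1500 ms (+)
```

Reading the output: each simulated subject blinks ~7/min (about 57 blinks
per 8-minute run after the 3 s exclusion); the recovered vEOG morphology
matches the generator's configured group values; delta GFP rises after the
blink only in the blink condition, peaking at the planted 250 ms; the
post>pre source contrast is significant at the precuneus-proxy points with
all three control contrasts empty; and the VOI time course shows the
positive deflection near +250 ms followed by the negative deflection near
+700 ms, the signature this package exists to measure. The extra clusters
at the epoch margins are the deterministic delta-band filter response to
the planted pulse, shared across subjects (see the methods vignette).

A thin CLI over the same functions lives at `inst/cli/bro.R`
(`simulate | detect | pipeline` subcommands; YAML config via
`write_config()` / `read_config()`).

## File formats

Recordings are stored in HDF5: `/data` (channels × samples; MEG rows in
tesla, vEOG in microvolt), `/times`, `/sfreq`,
`/channels/{labels,types,positions,orientations,regions}`, and
`/geometry/{helmet_radius,conductor_radius,baseline}`. Blink events are CSV
(`t0_sample,t0_seconds,score`), cohort manifests are CSV
(`subject,recording,events,seed`), and configuration files are YAML with
`simulation:` and `analysis:` sections mirroring `bro_sim_config()` and
`bro_analysis_config()`.

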