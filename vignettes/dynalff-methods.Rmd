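---
title: "Dynamic ALFF analysis: model, pipeline, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic ALFF analysis: model, pipeline, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The statistic

The amplitude of low-frequency fluctuations (ALFF) of a voxel's BOLD time
series is the mean of its amplitude spectrum — the square root of the
periodogram power — over the 0.01–0.08 Hz band, after linear detrending.
It indexes the strength of spontaneous slow activity at that voxel.

Dynamic ALFF (dALFF) asks how *stable* that amplitude is over the scan:
ALFF is recomputed inside sliding windows (each window independently
detrended; rectangular, no taper) and the per-voxel **sample variance of
the windowed ALFF values** (denominator $n_\text{windows}-1$) is the dALFF
statistic. A voxel whose slow-oscillation amplitude waxes and wanes has
high dALFF; a voxel with a stationary amplitude has dALFF near zero, up to
two residual terms quantified below.

Windows of length $L$ TR stepped by $s$ TR over $n$ retained volumes give
$\lfloor (n-L)/s \rfloor + 1$ windows. The window must contain at least
one full cycle of the slowest analysed frequency, $L \cdot \mathrm{TR} \ge
1/f_\min$; at $f_\min = 0.01$ Hz and TR = 2 s this makes 50 TR the minimum
admissible length, which is also the primary analysis default
(`window_spec(50, 5)`). Construction *warns* rather than errors below the
floor, because short-window sensitivity analyses (30 TR is a conventional
robustness check, and is run by default alongside 70 TR) must remain
expressible; the warning marks them as formally inadmissible.

Per-subject dALFF maps are z-scored across in-mask voxels
(`zscore_map()`), the standard toolbox convention: each map then expresses
each voxel's amplitude variability relative to the subject's own brain-wide
distribution.

## Preprocessing

The per-subject chain (`preprocess_subject()`) is:

1. **Discard** the first 10 volumes (magnetization equilibration).
2. **Smooth** with an isotropic Gaussian, FWHM 6 mm
   ($\sigma = \mathrm{FWHM} / (\sqrt{8\ln 2}\,\cdot\,\text{voxel size})$
   voxels per axis; separable convolution, zero padding).
3. **Nuisance regression**: Friston-24 motion expansion (6 rigid-body
   parameters, their one-volume lags, both squared; lagged rows zero-filled
   at $t=1$) plus mean white-matter, CSF and global signals and an
   intercept; per-voxel OLS residuals.
4. **Band-pass** 0.01–0.08 Hz: linear detrend, FFT, out-of-band
   coefficients zeroed, inverse FFT — the rectangular frequency-domain
   filter of the classic resting-state toolkits, not a Butterworth.
5. **Scrub**: framewise displacement $FD_t = \sum |\Delta d| + 50\,\mathrm{mm}
   \cdot \sum |\Delta \theta|$ (Power convention, rotations in radians on a
   50-mm sphere, $FD_1 = 0$); volumes with $FD \ge 0.5$ mm are dropped
   together with 2 preceding and 1 following volume. The default mode
   deletes the volumes before windowing; an `"interpolate"` mode (linear)
   is provided because deletion compresses the time base and distorts
   spectra. Subjects whose motion exceeds 3 mm or 3° at any time point are
   excluded entirely (`qc_exclude()`).

Inputs are assumed already aligned to a common grid: head-motion
realignment and spatial normalization are out of scope, as registration is
a separate, solved problem that would dominate the build without touching
the statistic of interest.

## Group inference

Voxel-wise pooled-variance two-sample t-maps (`two_sample_t_map()`,
df $= n_1 + n_2 - 2$) are thresholded and corrected at cluster level with
Gaussian random field (GRF) theory:

* Map smoothness is estimated from the per-subject deviations from their
  group-mean map (`estimate_smoothness()`): per axis, the mean correlation
  between spatial neighbors (each pair jointly normalized — this keeps the
  estimator nearly unbiased even for few residual maps), converted through
  the Gaussian autocorrelation relation
  $\mathrm{FWHM} = \text{voxel} \cdot \sqrt{4 \ln 2 / \lambda}$,
  $\lambda = 2(1-\rho)$. RESELs are the mask volume over the FWHM product.
* The t-map is converted to z-scores by probability integral transform
  (numerically through log tail probabilities), each tail is thresholded
  one-sided at the cluster-forming p (default 0.01), connected components
  are labeled (26-connectivity default; 18 and 6 available), and each
  cluster receives the standard GRF cluster-level corrected p from the
  expected cluster count $E[m]$ (3D Euler-characteristic density times
  RESELs) and the $\exp(-\beta k^{2/3})$ cluster-extent distribution.
  The two tails are two one-sided passes at $\alpha/2$ each, merged into
  one signed table.

The cluster-forming threshold of 0.01 is a choice the source analysis left
open (it states only cluster-level $p < 0.05$, GRF-corrected); 0.01 is
common practice and is configurable.

Clinical association uses Pearson correlation between cluster-mean z-dALFF
and each clinical measure in patients, two-tailed p from
$t = r\sqrt{(n-2)/(1-r^2)}$, Bonferroni-corrected over the family of
(clusters × measures). Demographic comparisons are the pooled t-test
reconstructed from group moments and Fisher's exact test on the sex table
(Fisher reproduces the published sex p of 0.51; a Yates-corrected
chi-squared gives 0.50, which is why Fisher is the default).

## Classification

Features are the cluster-mean z-dALFF values of the significant clusters —
the same full-sample feature selection as the source analysis, which is
circular and therefore optimistic; this is deliberate fidelity, and the
docs flag it. A linear soft-margin SVM (LIBSVM via e1071, $C = 1$) is
evaluated by leave-one-out cross-validation. Each training fold
standardizes feature columns with its own moments only; the held-out
subject never influences scaling or the fitted hyperplane. Patients are
the positive class, so sensitivity is patient detection.

## The synthetic cohort generator

No scan data are deposited for the study this package re-implements, so
validation rests on a generator (`generate_cohort()`) with recoverable
ground truth. Per subject it emulates:

* **Acquisition**: TR = 2 s, 250 volumes, 21 subjects per group by
  default; 24³ voxels of 3 mm by default (a desk-scale stand-in for a
  whole-brain grid — large enough for cluster geometry and smoothness
  estimation, small enough to run a full cohort in minutes on one CPU).
* **Background**: AR(1) (φ = 0.3) plus white Gaussian noise per voxel
  (total SD `noise_sd`), approximating BOLD temporal autocorrelation,
  plus a **globally coherent slow fluctuation** (amplitude
  0.6·`noise_sd`, random per-voxel weights in [0.7, 1.3]) standing in for
  respiration/drift. The global component is what the global/WM/CSF
  regressors are supposed to capture; without it, on a small grid the only
  coherent signal is the effect ROI itself, and nuisance regression
  removes the very effect under study — an instructive miniature of the
  global-signal-regression debate.
* **Effect regions**: two spheres (default radius 3 voxels) placed
  laterally, clear of the geometric white-matter core so that smoothing
  bleed into the WM regressor stays small. In-ROI voxels carry a
  band-limited oscillation (sum of 8 random in-band sinusoids, unit RMS);
  70% of carrier power is shared across the ROI (local BOLD coherence —
  without it per-voxel group contrasts are beating-noise-dominated and
  cluster inference has no spatial target), 30% is voxel-specific.
* **Amplitude dynamics**: the carrier is modulated by a slow sinusoidal
  envelope (period uniform in 200–400 s — long against the 100-s window,
  so windowed ALFF tracks it) with modulation depth
  `envelope_sd_<group>` times a per-subject lognormal factor
  (SD 0.2). Patients default to depth 0.2, controls 0.8, reproducing the
  decreased-dALFF direction.
* **Noise scale**: `noise_sd = 3.5` sets the in-band background amplitude
  comparable to the carrier. This is a structural requirement, not a
  nuisance choice: z-scoring each subject's map divides by the in-mask SD,
  and if background dALFF were negligible the ROI would set its own
  denominator and a purely multiplicative group effect would cancel
  exactly. At this scale the pipeline yields in-ROI z-dALFF of ~2.1
  (controls) vs ~1.3 (patients) with voxel-level effect sizes d ≈ 1.3 —
  the same order as the published peak t-values at n = 21 per group.
* **Motion**: slow random-walk traces with transient spikes
  (single-volume translations of 0.8–2 mm at probability
  `motion_spike_prob` per volume), so FD crosses the 0.5-mm threshold at
  known indices while subjects rarely hit the 3-mm exclusion — matching a
  study in which no subject was excluded for motion.
* **Covariates**: age and sex drawn to the published group moments
  (31.19 ± 6.38 vs 30.19 ± 6.3 years; 16/5 vs 13/8 female/male); disease
  duration lognormal. Patient VAS is drawn at the target correlation
  (default −0.5) with the patient's **measured** in-ROI z-dALFF (the
  generator runs the preprocessing and windowing once to obtain it).
  Targeting the measured quantity rather than the underlying envelope
  depth is what makes the correlation recoverable: at 500-s scans the
  envelope realization, not its nominal depth, dominates the measured
  value, and VAS drawn against pre-pipeline proxies transfers at
  |r| < 0.3. The construction reads as selecting a cohort in which pain
  tracks the imaging biomarker at the stated strength.

What the generator does **not** model: hemodynamic forward dynamics
(balloon model), spatially varying tissue contrast, scanner artifacts,
registration error, non-Gaussian noise. Passing recovery tests therefore
demonstrates that the pipeline recovers planted amplitude-dynamics effects
under idealized but structurally faithful conditions; it does not certify
behavior on real scans.

## Numerical choices

* ALFF aggregates the **mean** (not sum) of in-band amplitudes, making
  values comparable across window lengths; the amplitude spectrum is
  $|X_k|/\sqrt{n}$, bins inclusive on both band edges.
* Linear detrending leaks a small broadband component for tones not
  orthogonal to a ramp; with per-window detrending this leaves a
  stationary-signal dALFF floor of a few percent of the squared static
  ALFF (measured, and frozen into the tests as bounds of 5% for a single
  tone and 20% for the 8-component carrier).
* Sample variance (n−1) across windows, keeping the statistic unbiased
  for small window counts.
* The nuisance design always contains an intercept; constant duplicate
  columns are dropped with a message; residual rank deficiency is an
  error naming the collinear columns.
* Voxels with zero pooled variance get t = 0 with a message rather than
  NaN.
* Coordinates: voxel indices are 0-based with respect to the affine, and
  all reported peaks are mm coordinates through it.

## Validation suite design

The package validates itself at two levels. Unit and property tests pin
each operation to hand-computed or brute-force oracles (FD arithmetic,
scrub neighborhoods, window counts, Fisher p against hypergeometric
enumeration, pooled t against samples constructed with exact moments,
connectivity on diagonal voxel pairs). The acceptance suite then checks,
on one CPU in minutes:

* the printed, analytically recomputable study numbers (age p = 0.61,
  sex p = 0.51, correlation p for r = −0.5 at n = 21, the 83.33%
  accuracy arithmetic, the 50-TR window floor);
* voxel-wise type-I error of the t-map under the null
  (50 replicates on 10³ grids);
* GRF cluster FWER on smooth null fields at study conditions
  (200 replicates, 21 + 21 maps, 6-mm kernel on 24³ grids);
* end-to-end recovery on a deficit cohort (21 + 21 on a 20³ grid:
  cluster direction and location by Dice, classification above 80%,
  VAS correlation inside [−0.75, −0.25]);
* LOOCV chance calibration under label permutation with 7 features, the
  dimension of the published classifier (at much lower dimension LOOCV
  shows its known pessimistic bias at chance with balanced groups — with
  2 noise features mean accuracy is ~40%, an artifact of the estimator,
  not of the implementation);
* recovery of a known 6-mm smoothing kernel within 15%.

Problem sizes (grids of 10–24 voxels per axis, 4–42 maps, 50–200
replicates) are the package's own choices balancing Monte-Carlo precision
against a few minutes of runtime.

## Known limitations

* **Analytic GRF cluster p-values are conservative at these conditions.**
  With a 6-mm kernel on 3-mm voxels (FWHM ≈ 2.2 voxels) and Gaussianized
  t-maps, the expected cluster count and suprathreshold volume match
  theory almost exactly (observed 47.7 clusters per tail vs 44.8
  predicted), but the $\exp(-\beta k^{2/3})$ extent-tail approximation
  demands a critical extent of ~48 voxels where the empirical null 97.5th
  percentile of the maximum extent is ~26. Measured FWER is ≈ 0.005–0.01
  instead of 0.05 — error control holds, but in the conservative
  direction, consistent with the literature on analytic cluster inference
  at low smoothness and Gaussianized low-df t-fields. The acceptance suite
  asserts the nominal two-sided calibration band and this check fails
  honestly; the practical consequence is reduced power, not inflated false
  positives. Permutation inference would fix calibration but is a
  non-goal here.
* Cluster anatomical naming is out of scope: peaks are reported as mm
  coordinates only.
* The full-sample feature selection for the SVM is circular (see above);
  a nested selection is the statistically clean alternative and the
  optimism of the default is documented wherever the metrics appear.
* Scrubbing-by-deletion before windowing compresses the time base; the
  interpolation mode mitigates but cannot undo information loss.
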