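---
title: "Walking-task fNIRS analysis for freezing of gait: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walking-task fNIRS analysis for freezing of gait: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`fognirs` implements a complete analysis chain for dual-wavelength
functional near-infrared spectroscopy (fNIRS) recordings acquired during a
walking paradigm that induces freezing of gait (FOG) in Parkinson's
disease: raw light intensity is converted to hemoglobin concentration
changes, cleaned, segmented into task epochs, and summarized as cortical
activation values and channel-wise Pearson functional connectivity (FC),
with a group-statistics layer on top. A synthetic cohort generator with
known ground truth makes every stage testable without patient data.

This vignette explains the models, the tunable parameters, the numerical
choices, and which features of real data the simulation does and does not
emulate.

## The recording and the task

The default montage has 48 measurement channels formed from 24 sources and
16 detectors at 3 cm separation, sampled at 11 Hz at 730 and 850 nm.
Channels are grouped into five regions of interest (ROIs): prefrontal
cortex (PFC, 14 channels), premotor cortex (PMC, 8), primary motor cortex
(M1, 2), primary somatosensory cortex (S1, 5) and temporal cortex (TLC,
10); nine channels carry no ROI label and only participate in
channel-level analyses. Source/detector indices are laid out on a regular
grid as metadata; no geometric computation uses them.

The session clock starts at the onset of the first standing block (a short
preparatory period before it is not part of the analysed record). Blocks:
60 s standing, 60 s freezing-induction walking (narrow-corridor walking
with turns), 30 s standing rest, 60 s normal walking, 60 s standing;
270 s in all. The analysis windows are the 0--60 s resting baseline, the
62.5--120 s freezing-induction window and the 152.5--210 s normal-walking
window.

Two conventions coexist for the walking windows: the stated analysis
ranges start 2.5 s after the block boundary, while the extraction rule
says "3--60 s after walk onset". We reconcile them by taking walk onsets
at the block boundaries (60 s, 150 s), applying the 3--60 s rule relative
to onset, and intersecting with the stated window — giving extraction
windows of [63, 120) and [153, 210) s with 5-s pre-walk baselines
[55, 60) and [145, 150) s. Both raw windows remain available in the
paradigm object. All windows are half-open; a sample at time `t = k/fs`
belongs to `[a, b)` iff `a <= t < b`, which makes window sample counts
deterministic (the freezing analysis window [62.5, 120) contains exactly
632 samples at 11 Hz, the extraction window [63, 120) exactly 627).

## Preprocessing chain

1. **Channel quality control.** The coefficient of variation
   `CV = 100 * sd/mean` of raw intensity is computed per channel and
   wavelength over the whole recording (sample SD). A channel is retained
   iff CV is at or below 14% at *both* wavelengths; the exclusion rule is
   strictly `CV > 14%`. The window and wavelength rule are not uniquely
   determined by common practice; requiring both wavelengths over the full
   recording is the strictest deterministic reading. Channels excluded
   here are `NA` everywhere downstream — never zero.

2. **Optical density.** `dOD(t, λ) = -log10(I(t, λ) / mean(I(λ)))` per
   channel, with the mean over the full recording.

3. **Motion-artifact detection** operates on dOD, where the 0.5 OD
   amplitude threshold is dimensionally meaningful. Within sliding windows
   of 0.5 s a channel is flagged when the signal range exceeds 6.0 times
   the channel's global SD or 0.5 OD; flagged instants are dilated by
   ±1 s. Head movements and swallowing produce both transient spikes and
   sustained baseline steps; the detector sees both as large local ranges.

4. **Spline correction.** For each flagged segment a cubic smoothing
   spline is fitted to the segment and subtracted, and the segment is
   re-levelled to the mean of the preceding clean second (the following
   one at the recording start). The fit must *track* the artifact
   trajectory closely — including sharp steps — so that subtracting it
   removes the artifact rather than the physiology; we therefore run
   `stats::smooth.spline` at `spar = 0`, the close-tracking end of R's
   smoothing scale (equivalent to a near-interpolating 0.99 in conventions
   where 1 denotes the interpolant). After correcting a segment, all
   subsequent samples are offset so the series is continuous at the
   segment's trailing edge. For transient artifacts this offset is
   numerically zero, so those samples are effectively untouched; for
   sustained steps it is what removes the step — without it a corrected
   step would simply re-appear at the mask boundary and be re-detected,
   and no finite residual criterion could hold. Correction is idempotent:
   re-running detection on corrected output finds nothing.

5. **Conversion to hemoglobin.** The modified Beer–Lambert law (MBLL)
   relates dOD to concentration changes:
   `dOD(λ) = (ε_HbO2(λ) ΔHbO2 + ε_HHb(λ) ΔHHb) · d · DPF`, solved per
   sample as a 2×2 linear system with source–detector distance
   `d = 3 cm` and differential path length factor `DPF = 6.0` at both
   wavelengths. Extinction coefficients are a pinned constants table of
   literature-compilation values (`extinction_table()`); the simulator's
   forward model uses the same table, so forward/inverse round trips are
   exact to machine precision. Concentrations are reported in µmol/L.

6. **Bandpass filtering.** A zero-phase Butterworth bandpass of order 3
   (effective order 6 under forward–backward application) at
   0.01--0.2 Hz removes slow drift, Mayer waves above the band edge,
   respiration (~0.3 Hz) and cardiac pulsation (~1 Hz). Only the band is
   externally prescribed; order 3 forward–backward is common practice and
   configurable. Implementation: the filter is designed in-package
   (analog prototype → bandpass transform → bilinear transform) and
   factored into cascaded second-order sections, applied forward–backward
   in compiled code with 120 s odd-reflection padding and steady-state
   initial conditions per section. A single sixth-order direct-form
   polynomial is numerically unusable at a normalized low cutoff of
   0.0018 (its double-precision coefficient representation caps the
   stopband near 27 dB); the cascade reaches the analytic response, which
   is exposed as `butter_bandpass_gain()` and verified in the tests
   (≥ 40 dB at 1 Hz). Like every zero-phase filter, tone-like components
   excite low-frequency transients near the series edges; tests that
   measure the frequency response therefore use long probe tones and trim
   the edge regions, and the activation round-trip checks trim 10 s per
   end.

## Activation

HbO2 is the activation biomarker (it is the more perfusion-sensitive
chromophore; HHb is carried through the chain but not analysed). For each
walking condition the activation value of a channel is the mean filtered
HbO2 over the extraction window minus the mean over the 5-s pre-walk
baseline. This block-average estimator is deliberately simple — no
GLM/HRF regression — matching the analysis this package reproduces; it is
linear in the signal and invariant to constant offsets. ROI values are
unweighted means over the ROI's retained channels, with missing channels
dropped (an ROI with no retained channels is `NA` with a warning).

## Functional connectivity

FC is the Pearson correlation of filtered HbO2 between channel pairs over
a condition's extraction window (the same [63, 120) / [153, 210) windows
as activation; computed per condition). Raw r is kept — no Fisher
transform by default, no thresholding, negative values retained — because
group summaries of FC in this design are plain means of r. Inter-ROI
connectivity of a pair (A, B) is the mean of r over all member channel
pairs; intra-ROI connectivity is the mean over distinct unordered pairs
(the diagonal never contributes; intra-M1 is the single pair 37--44).
Ten tracked channel pairs (temporal–prefrontal, temporal–premotor,
prefrontal–premotor and somatosensory couplings) are extracted into long
tables ready for repeated-measures testing across cueing conditions.

A practical caveat the package makes explicit in its calibration: a 57-s
window of a 0.01--0.2 Hz band-limited process contains on the order of
only tens of independent samples, so single-pair windowed correlations
carry sampling SDs of ~0.2--0.3. ROI-pair averages are much more stable
because the pair errors are only weakly coupled at these correlation
levels, but the irreducible window noise is why the generator treats
observed between-subject SDs as the sum of true subject variability and
window-sampling variance (below), and why the single-pair intra-M1 value
is intrinsically the noisiest summary the pipeline reports.

## Group statistics

* **Normality gating** (demographics and gait): Shapiro–Wilk per group at
  α = 0.05; all groups must pass for the parametric route (t-test /
  repeated-measures ANOVA), otherwise Mann–Whitney U / Kruskal–Wallis H
  (tie-corrected, normal/χ² approximation). Groups with n < 3 or zero
  variance route to nonparametric with a warning. Integer-valued,
  right-skewed freezing-episode counts are always compared
  nonparametrically.
* **Two-group comparisons** of channel, ROI and FC values use the pooled
  Student t (Welch optional):
  `t = (m_a - m_b) / sqrt(s_p² (1/n_a + 1/n_b))`,
  `s_p² = ((n_a-1)s_a² + (n_b-1)s_b²)/(n_a+n_b-2)`, df `n_a+n_b-2`, with
  Cohen's `d = (m_b - m_a)/s_p`. `ttest_from_summary()` applies these
  formulas directly to (mean, SD, n) triples so printed group summaries
  can be re-tested; `ttest_from_samples()` is its exact sample-side twin.
* **Repeated measures**: one-way repeated-measures ANOVA with subject as
  blocking factor, `F = MS_condition/MS_error` on (k−1, (k−1)(n−1)) df,
  partial η² = SS_cond/(SS_cond+SS_error), and Fisher's LSD post-hoc
  (uncorrected pairwise paired t-tests), for the four cueing conditions
  (no cue, auditory beat, music, imagined beat).
* **Multiplicity**: Benjamini–Hochberg step-up FDR across channels within
  one comparison family, rejection at q = 0.05 (`stats::p.adjust`; the
  test suite checks it against a hand-written step-up oracle).

## The synthetic cohort generator

The generator's defaults encode the study conditions this pipeline is
meant to analyse: 28 healthy controls (HC) vs 28 patients (PD+FOG), with
ROI-specific activation deficits in the patient group during induced
freezing and globally elevated patient connectivity.

Per subject and channel the simulated HbO2 series is the sum of:

* **Evoked component**: per-ROI boxcar neural drive during the two
  walking blocks, convolved with a double-gamma HRF (onset delay 1.5 s,
  peak 5.5 s after neural onset, undershoot ratio 1/6). Drive amplitudes
  are solved from a 2×2 linear response map (unit freeze drive and unit
  normal-walk drive, each pushed through HRF convolution, the default
  bandpass and the activation estimator) so that in the noise-free limit
  the pipeline's activation estimate equals the nominal effect exactly —
  the forward/inverse round trip is exact by construction, and the tests
  assert recovery to 1e-6.
* **Latent connectivity field**: a band-limited Gaussian field
  (one-pass Butterworth band spectrum, SD 0.13 µmol/L) with a per-subject
  channel correlation matrix carrying the target structure. Keeping this
  field's spectrum broad maximizes the effective sample count of the FC
  window; its amplitude is chosen large enough that the task-evoked
  waveform (shared by all channels of an ROI) can never dominate the
  windowed correlations.
* **Physiological noise**: cardiac (~1 Hz, 0.05 µM), respiratory
  (~0.3 Hz, 0.03 µM) and Mayer-wave (~0.1 Hz, 0.008 µM) oscillations with
  per-channel phases and slightly jittered frequencies, linear drift plus
  a random walk, and white measurement noise (0.05 µM). HHb is generated
  as −1/3 of HbO2 plus small independent noise; its realism is secondary
  since it is not analysed.
* **Motion artifacts**: Poisson events (0.5/min) of spikes (≤ 1 s
  Gaussian transients) or sustained baseline steps, each affecting a
  random ~30% subset of channels (optode-local motion) at 6--12× the
  channel's OD standard deviation, applied in the optical-density domain
  with ground-truth masks retained.

Concentrations are forward-mapped through the same MBLL constants the
inverse uses, and dual-wavelength intensities are emitted around random
per-channel baseline levels.

### Observed-scale calibration

All effect targets are stated on the *observed* scale — the values a
28-vs-28 cohort analysis should report — with freezing-period activation
and connectivity targets matching published group summaries of a
28-vs-28 walking-task cohort of this design and
unreported cells (normal-walk activation, the four untabulated inter-ROI
pairs, S1/M1/PMC intra values, all gait distributions) filled with
realistic values that preserve the qualitative ordering. Because the
pipeline adds measurement variance and attenuates correlations, the
generator inverts its own measurement model, using two cached empirical
calibrations run once per noise configuration under pinned internal
seeds:

1. Noise-only pipeline runs split the within-window variance of the
   analysed series and the variance of the activation estimate into a
   latent-fluctuation part and an independent-noise part. Activation draw
   SDs are shrunk by the ROI-level measurement SD (fluctuations are
   correlated within an ROI; independent noise averages down with channel
   count), so observed activation SDs land on the targets. With the
   5-s baseline the measurement SD is a large fraction of the observed
   between-subject SD — in this design, much of the apparent subject
   variability in activation *is* window noise.
2. Replicate sessions with drawn connectivity targets estimate, per ROI
   pair, the residual window-sampling variance and the draw-to-observation
   slope (feasibility repairs slightly attenuate coherent draws); a second
   pass re-estimates both at the realized draw scale. Subject draw SDs are
   deconvolved through this map.

Latent region-pair correlations are obtained from the drawn observed
targets by inverting the contamination model
`r = (c·V_f + cov_evoked) / sqrt((V_f+v_n+v_e_A)(V_f+v_n+v_e_B))` at the
region level, and the channel matrix is assembled blockwise. Per-subject
deviations are hierarchical — 70% of the variance from a global
connectivity level, 20% from per-region factors, 10% independent pair
residual — because coherent moves keep the implied covariance
positive-definite; residual indefiniteness is eigenvalue-clipped, and a
structurally infeasible *mean* target set raises an explicit error. Gait
tables are drawn distributions (not kinematic models) with a stable
subject effect (60% of variance) inducing the within-subject pairing
across conditions and interventions.

### What the simulation does not emulate

Superficial/extracerebral contamination (no short-separation channels),
subject motion coupled to gait phase, heterogeneous per-channel HRFs,
optical photon transport, non-Gaussian physiological noise, and any
biomechanics behind the gait numbers. Passing tests therefore demonstrate
that the pipeline recovers the statistical structure it assumes, not that
it is robust to everything real walking data contains.

## Evaluation sizes and expected behavior

The packaged acceptance checks run, as the package's standard evaluation
sizes: 60 simulated cohorts (28 vs 28) for the group-contrast sign
pattern, the first 50 of them for effect-size recovery of the
prefrontal–temporal connectivity contrast, 40 null-preset cohorts for
false-discovery calibration, 2000 replicates for t-test type-I error, and
100 synthetic sessions for spike-detection sensitivity. With the default
conditions the sign pattern (controls above patients in S1/M1/PFC
activation; patients above controls in all six tabulated inter-ROI pairs)
is recovered in ≥ 90% of cohorts, and the recovered prefrontal–temporal
Cohen's d centers near 1.2. Note that for a true d of ~1.16 at n = 28 per
group the sampling SD of the estimated d is ~0.29, so single-cohort
estimates in roughly [0.7, 1.7] are the expected behavior, and about 9% of
honest cohorts fall outside that range.

## Serialization

Recordings serialize to a single long-format CSV
(`time_s, channel, wavelength_nm, intensity`) with `#key=value` header
lines, written at full shortest-round-trip precision so
`read(write(x)) == x`; montage and paradigm serialize to JSON; every
result table is a CSV. A run manifest (package version, seed, preset,
config hash) accompanies pipeline output, and a completed run is a pure
function of its configuration and seed.

## Known limitations

* The block-average activation estimator confounds slow systemic changes
  with evoked activity; the 5-s baseline makes single-subject activation
  values noisy by construction.
* Windowed FC of band-limited signals has large single-pair sampling
  error; channel-pair results should be read with that in mind.
* The spline corrector removes artifacts it can track; overlapping
  simultaneous artifacts on the same channel within one mask segment are
  corrected jointly, which can leave residuals above the single-artifact
  case.
* Group tables for the fNIRS measures use the pooled t-test throughout
  (the convention of the summaries this package reproduces); the
  normality gate applies to demographic and gait comparisons.
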