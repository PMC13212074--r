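# fognirs

Analysis of dual-wavelength functional near-infrared spectroscopy (fNIRS)
recordings from walking tasks that induce freezing of gait (FOG) in
Parkinson's disease. The package takes raw 48-channel light-intensity
recordings of a stand / freezing-induction walk / rest / normal walk
paradigm and produces cortical activation and functional-connectivity
group statistics, for researchers studying gait-related cortical
dysfunction and rhythmic auditory cueing interventions. A synthetic
cohort generator with known ground truth makes the whole chain testable
without patient data.

## What it computes

**Preprocessing.** Channel quality control by coefficient of variation
(exclude if CV > 14% at either wavelength), optical-density conversion
`ΔOD = -log10(I/Ī)`, motion-artifact detection (sliding-window range vs
6×SD and 0.5 OD thresholds) with cubic-spline correction, conversion to
hemoglobin concentration changes via the modified Beer–Lambert law

```
ΔOD(λ) = (ε_HbO2(λ)·ΔHbO2 + ε_HHb(λ)·ΔHHb) · d · DPF      d = 3 cm, DPF = 6
```

solved per sample as a 2×2 system, and a zero-phase Butterworth bandpass
(0.01–0.2 Hz, order 3 applied forward–backward).

**Activation.** Per channel and condition, mean filtered ΔHbO2 over the
task extraction window (3–60 s after walk onset) minus the 5-s pre-walk
baseline; unweighted ROI means over the prefrontal (PFC), premotor (PMC),
primary motor (M1), somatosensory (S1) and temporal (TLC) channel groups.

**Connectivity.** Channel×channel Pearson r of ΔHbO2 over each
condition's window, aggregated to the 10 inter-ROI and 5 intra-ROI means
and to tracked channel pairs.

**Group statistics.** Pooled-variance Student t with Cohen's
`d = (m₂−m₁)/s_p` (from samples or directly from printed mean ± SD
summaries), Shapiro–Wilk-gated nonparametric alternatives (Mann–Whitney
U, Kruskal–Wallis H), one-way repeated-measures ANOVA with partial η² and
LSD post-hoc for the cueing conditions, Benjamini–Hochberg FDR across
channels, and paired gait comparisons (cadence, stride length, velocity,
swing width, foot progression angle, freezing-episode counts).

## Worked example

Re-test a published group summary directly from its printed values
(healthy controls 0.124 ± 0.112 vs patients 0.239 ± 0.171, n = 28 each):

```r
library(fognirs)
ttest_from_summary(0.124, 0.112, 28, 0.239, 0.171, 28)
#> t_pooled_summary: statistic = -2.977, df = 54, p = 0.004351, cohens_d = 0.796
```

The negative t and d ≈ 0.8 say the patient group's somatosensory–
prefrontal coupling exceeds the controls' by about 0.8 pooled standard
deviations.

Run the full simulate → preprocess → analyse pipeline on a small cohort
(8 subjects per group; the default study size is 28):

```r
out <- run_pipeline(default_config(n_per_group = 8, seed = 42))
out$tables$activation_roi[, c("label", "hc_mean", "pd_mean", "statistic", "effect", "p")]
#>   label hc_mean  pd_mean statistic  effect      p
#> 1   PFC  0.0453 -0.0419     2.306 -1.1528 0.0369
#> 2   PMC  0.0411  0.0335     0.251 -0.1256 0.8053
#> 3    M1  0.0474 -0.0053     1.135 -0.5676 0.2754
#> 4    S1  0.0758  0.0200     1.599 -0.7995 0.1321
#> 5   TLC  0.0598  0.0650    -0.131  0.0655 0.8977
```

Rows are freezing-induction ΔHbO2 activation (µmol/L) per region:
healthy controls activate PFC/S1/M1 during induced freezing while the
simulated patients do not (positive t, negative d = control > patient);
the temporal cortex shows no deficit. Connectivity runs the other way —
patients above controls:

```r
out$tables$fc_inter[c(3, 4, 10), c("label", "hc_mean", "pd_mean", "statistic", "effect", "p")]
#>      label hc_mean pd_mean statistic effect      p
#> 3   PFC-S1  0.1163   0.200     -1.28  0.642 0.2202
#> 4  PFC-TLC  0.0128   0.155     -2.32  1.159 0.0360
#> 10  S1-TLC  0.0446   0.185     -2.18  1.090 0.0468
```

and the paired gait contrast shows the freezing signature (slower, shorter
strides, wider sway):

```r
out$tables$gait_freeze_vs_normal[2:4, ]
#>       parameter     test statistic df        p effect
#> 2 stride_length paired_t     -6.90  7 0.000232 -2.439
#> 3      velocity paired_t     -4.52  7 0.002744 -1.597
#> 4   swing_width paired_t      2.20  7 0.063445  0.779
```

`run_pipeline(..., out_dir = "results")` additionally writes every table
as CSV plus per-subject measures and a run manifest; a thin command-line
wrapper lives at `inst/scripts/fogpipe.R`
(`Rscript fogpipe.R run-all --n-per-group 28 --seed 1 --out dir`).

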