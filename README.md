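# neckcore

Analysis pipeline for surface-EMG and kinetics studies of cervical "core
stabilization" during locomotion: do the superficial neck muscles act to
stabilize the head against inertia, or are they part of the linked chain of
axial muscles that stabilizes the pelvis against the torques the leg
muscles apply at the hip?

The package is aimed at biomechanics and electrophysiology researchers who
record multi-channel trials — surface EMG of cervical muscles, neck and
foot accelerometers, vertical ground-reaction force — during treadmill
running and countermovement jumps under force manipulations (added head
mass, horizontal pulls at the waist, added downward "gravity" force), and
who need the full processing chain from raw channels to corrected
condition-comparison tables. Because studies of this design rarely deposit
raw recordings, the package also ships a synthetic multi-subject study
generator with known ground truth, so every stage of the pipeline is
verifiable end to end.

## What it computes

**EMG activation.** Each EMG channel is full-wave rectified; the resting
background (mean of the 500 smallest rectified samples of a supported-head
rest trial) is subtracted and clipped at zero; amplitudes are normalized to
%MVC against a per-subject reference — the mean over the four
maximum-voluntary-contraction trials of the maximum of a 250-ms moving
average of the rectified trace. Running trials are segmented into
locomotor cycles at right-foot strikes (detected from a foot
accelerometer), jumps into an onset-to-landing window from the force
trace. Cycles are integrated (trapezoid, %MVC·s) and time-normalized into
100 bins (200 for jumps); the hierarchy is cycles → subject mean →
across-subject mean with t-based 95% CI.

**Condition comparisons.** For subject *s* and muscle *m*, the activation
ratio is

&nbsp;&nbsp;&nbsp;&nbsp;R<sub>sm</sub> = Ī<sub>sm</sub>(manipulation) / Ī<sub>sm</sub>(control),

where Ī is the mean per-cycle integrated activation. Group tables report
mean ± SD of R across subjects with a paired, one-tailed Wilcoxon
signed-rank test of the underlying measures (exact null distribution up to
n = 25 without ties) under Holm–Bonferroni step-down correction over the
eight-muscle family. Pull-plus-head-mass conditions are compared against
the matching pull condition, not against control.

**Kinematics and jump kinetics.** Accelerometer traces are smoothed with a
10-ms rolling mean, gravity-calibrated, baselined from the flight phase
(vertical) or by condition-specific rules (fore-aft), and summarized per
step (peaks, whole-step and half-step means, optional cosine tilt
correction). Jump trials use the impulse–momentum method: with effective
weight W from quiet standing,

&nbsp;&nbsp;&nbsp;&nbsp;J = ∫<sub>onset</sub><sup>takeoff</sup> (F(t) − W) dt = m·v<sub>takeoff</sub>,&nbsp;&nbsp;&nbsp;&nbsp;h = v<sub>takeoff</sub>² / 2g,

with phases detected from the force trace (sustained unweighting onset,
10 N takeoff threshold, 10%-of-weight landing). Graded-effort jumps feed a
least-squares exponential fit y = a·exp(b·J) of integrated EMG against net
impulse.

## Worked example

Generate a seeded six-subject study with control and forward-pull running
trials (the generator's default effect multipliers are the reported group
means, e.g. 3.63 for the sternohyoid under forward pull), then run the
running pipeline:

```r
library(neckcore)
cfg   <- synthetic_config(n_subjects = 6, seed = 42, n_cycles = 20)
study <- generate_study(cfg, conditions = c("control", "forward_pull"))
res   <- run_running_analysis(study)
print(res$comparisons$forward_pull_vs_control, digits = 3)
```

```
               muscle n ratio_mean ratio_sd  p_raw tested p_adjusted reject
1         sternohyoid 6       3.62  0.02602 0.0156   TRUE      0.125  FALSE
2 sternocleidomastoid 6       2.72  0.02378 0.0156   TRUE      0.125  FALSE
3            masseter 6       1.52  0.00841 0.0156   TRUE      0.125  FALSE
4    levator_scapulae 6       1.77  0.01071 0.0156   TRUE      0.125  FALSE
5     upper_trapezius 6       1.23  0.00406 0.0156   TRUE      0.125  FALSE
6    splenius_capitis 6       1.50  0.01205 0.0156   TRUE      0.125  FALSE
7      semispinalis_r 6       1.33  0.01311 0.0156   TRUE      0.125  FALSE
8      semispinalis_l 6       1.30  0.01167 0.0156   TRUE      0.125  FALSE
```

Every recovered group-mean ratio sits on its configured effect size
(column `ratio_mean` against the generator's multipliers): the pipeline is
unbiased at this noise level. With six subjects the smallest attainable
one-tailed exact p is 1/2⁶ ≈ 0.016, which Holm's first step multiplies by
eight — hence `p_adjusted = 0.125` and no rejections; the full 16-subject
design is needed for significance, exactly as in a real study of this
size. The kinematics summary from the same study,

```r
run_kinematics_analysis(study)$summary
```

```
     condition n vertical_mean vertical_sd fore_aft_mean fore_aft_sd
1      control 6          9.39     0.00105          2.27    0.000587
2 forward_pull 6         10.18     0.00186         -6.11    0.003998
```

reproduces the constructed condition means (control ≈ g vertically,
braking-only fore-aft acceleration under forward pull). Jump studies work
the same way through `run_jump_analysis()`, which returns per-trial
kinetics, Holm-corrected ratio tables for maximum/mean/integrated
activation, 200-bin ensemble profiles and the per-muscle exponential
effort fits.

## Package layout

- `R/signal-model.R` — channel/trial/event types, TSV+JSON trial bundles,
  YAML manifests, applied-force trial rejection
- `R/synthetic.R` — the synthetic study generator and its configuration
- `R/emg.R` — rectification, background, MVC normalization, segmentation,
  integration, binning, ensemble averaging
- `R/kinematics.R` — smoothing, gravity calibration, foot-strike
  detection, baselining, step statistics, tilt correction
- `R/jump.R` — jump phase detection and impulse–momentum kinetics
- `R/stats.R` — Wilcoxon signed-rank, Holm–Bonferroni, ratio tables,
  exponential fits
- `R/pipeline.R` — study-level orchestration and TSV output
- `vignettes/neckcore-methods.Rmd` — the methods vignette (model,
  assumptions, parameter choices, limitations)
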