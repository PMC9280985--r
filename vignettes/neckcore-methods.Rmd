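---
title: "Methods: cervical EMG and locomotor kinetics analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cervical EMG and locomotor kinetics analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neckcore)
```

## The problem and the design

During running and jumping, the muscles of the neck could be active for
two distinct reasons: *postural stabilization* — holding the head against
its own inertia as the body accelerates — or *core stabilization* —
forming part of the linked chain of axial muscles that fixes the pelvic
girdle against the torques the extrinsic leg muscles apply at the hip.
The two hypotheses make opposite predictions under force manipulations:
doubling the mass of the head should roughly double the postural demand
but leave the core demand unchanged; adding horizontal pulls at the waist
during running increases hip torques (core demand) on a specific side of
the neck in a specific half of the step; adding a downward force during
maximal jumps reduces body acceleration (postural demand) while leaving
the maximal hip torques unchanged.

`neckcore` implements the full measurement chain for this design:
surface-EMG activation measures locked to locomotor cycles or jump
phases, accelerometer and force-plate kinetics that verify what each
manipulation actually did to the body, per-subject manipulation/control
activation ratios, and the paired nonparametric testing procedure. A
synthetic study generator with known ground truth stands in for raw data,
which studies of this design typically do not deposit.

## EMG processing chain

Let $x(t)$ be a raw EMG channel sampled at $f_s$ (2000 Hz in the study
design). The chain is:

1. **Rectification**: $|x(t)|$.
2. **Background subtraction**: the resting background $b$ is the mean of
   the 500 smallest rectified samples of a rest recording taken with the
   head supported; activation is $\max(|x(t)| - b, 0)$. Clipping at zero
   is a package decision — negative activation is physically meaningless,
   and without clipping, integrated measures of near-silent muscles would
   be dominated by noise excursions below the background level.
3. **MVC normalization**: the reference is the mean over the available
   MVC trials (four per direction in the study design; ventral muscles
   against neck-flexion trials, dorsal against extension) of the maximum
   of a 250-ms centered moving average of the rectified,
   background-subtracted trace. The smoothing window is a package
   decision: a raw single-sample maximum is an order statistic of the
   noise, not of the contraction. 250 ms is long enough to average the
   carrier fluctuations of surface EMG and short enough to track a held
   maximal effort. Activation is expressed as
   $100 \cdot \max(|x| - b, 0) / \text{ref}$ (%MVC).
4. **Segmentation**: locomotor cycles are half-open windows between
   successive right-foot strikes, capped at 20 per trial (the number
   recorded in the design); jumps use the onset-to-landing window from
   the force trace.
5. **Integration and binning**: per-cycle trapezoidal integrals (%MVC·s),
   and time-normalized profiles of 100 bins per stride or 200 per jump.
   When the window length is not a multiple of the bin count, the
   remainder samples are assigned one each to the earliest bins.
6. **Hierarchy**: cycle profiles are averaged within a subject first;
   group profiles are mean ± $t_{0.975,\,n-1}\cdot\mathrm{SE}$ across
   subjects. The CI method is a package decision (the design reports
   95% CIs without naming a method); with 16 subjects the t- and
   normal-based intervals differ by ~7%.

The activation ratio for subject $s$, muscle $m$ is
$R_{sm} = \bar I_{sm}(\text{manip}) / \bar I_{sm}(\text{control})$ over
mean per-cycle integrals. A single per-subject MVC reference is used for
both conditions, so $R$ is invariant to the reference — ratios computed
on raw volts or on %MVC agree (the package enforces one reference per
subject/muscle for exactly this reason).

## Accelerometer kinematics

Accelerometer channels represent *proper acceleration*: an axis reads
$\approx g$ when static and vertical and $\approx 0$ in flight. All
traces are smoothed with a 10-ms centered rolling mean (21 samples at
2000 Hz) before any baselining or peak extraction — per-stride flight
minima on the raw trace would be single-sample noise minima. Calibration
is the two-point gravity procedure: gain $= 2g/(\bar V_{up} - \bar
V_{down})$, offset at the midpoint voltage.

Foot strikes are local maxima of the foot-accelerometer trace exceeding
median $+ 6\,\mathrm{MAD}$, with a refractory period of half the expected
stride period. The MAD threshold is scale-free, so detection is
invariant to amplitude calibration.

Sensor zero-offsets are removed per condition:

- **vertical**: mean of per-stride minima of the smoothed trace (the
  flight phase has zero proper acceleration);
- **fore-aft, control-like conditions**: mean over an integral number of
  cycles (braking and propulsion cancel);
- **fore-aft, forward pull**: mean of per-step *peaks* — the applied
  force is large enough that the runner never accelerates forward, so
  the most-forward acceleration in each step marks zero;
- **fore-aft, rearward pull**: mean of per-step *minima*, the mirror
  case.

Steps are obtained by splitting each stride at its temporal midpoint
(the contralateral footfall is not instrumented); per-step statistics
report peaks and whole-step and half-step means. The cosine tilt
correction (factor $\cos\theta$, e.g. 0.883 at a 28° lean, at most a 12%
underestimate at the largest lean observed in the design) is available
but **not** applied by default, matching the design's choice to report
rather than correct the underestimate.

## Jump kinetics

The impulse–momentum method at native sampling rate: with effective
weight $W$ (quiet-standing mean over the minimum-rolling-SD window —
which absorbs any constant applied downward force),
$a(t) = (F(t) - W)/m$, $v(t)$ its cumulative trapezoidal integral from
movement onset, net impulse $J = \int_{on}^{to} (F - W)\,dt = m\,
v_{to}$, and jump height $v_{to}^2/2g$ with the flight-time variant
$g\,t_f^2/8$ as a cross-check ($g = 9.81$ m·s⁻² throughout).

Phase detection is a package decision worth stating. A literal reading
of "onset when the force drops below 10% of body weight" would place the
onset essentially at takeoff, because the force is near body weight when
the countermovement begins; the package therefore defines onset as the
first *sustained* (≥ 50 ms) drop below 90% of effective weight — a 10%
unweighting — and keeps the literal rule behind a `literal_10pct` flag.
Takeoff is the first sample below an absolute 10 N (robust to plate
noise, unlike a %-of-weight rule near zero), landing the first return
above 10% of effective weight.

Signed percent impulse changes are reported alongside their magnitude:
with group means 203.7 and 159.5 N·s the change is +21.7% (a
reduction); with 203.7 and 210.5 N·s it is −3.3%, magnitude ≈ 3% — the
design's prose describes this pair both as "no change" and as a
"reduction by 3%", so the package refuses to guess a sign and reports
both quantities.

## Statistics

Paired one-tailed Wilcoxon signed-rank: differences manip − control,
zeros dropped (the classical treatment; the design does not state one),
absolute differences mid-ranked. For $n \le 25$ effective pairs without
ties the exact null distribution of $W^+$ is used; otherwise a normal
approximation with tie correction and continuity correction. The
direction is explicit per comparison and never inferred: running
manipulations test "greater" (all predicted increases), added-gravity
jumps test "less" (the postural prediction is a decrease), added-mass
jumps "greater". Holm–Bonferroni step-down correction is applied over
the eight-muscle family at $\alpha = 0.05$;
adjusted$_{(i)} = \max_{j\le i} \min(1, (m-j+1)p_{(j)})$ in sorted
order, mapped back to input order.

The EMG–effort relation is fitted as $y = a e^{bJ}$ by untransformed
nonlinear least squares (log-space regression would re-weight errors
toward small $y$), initialized from a log-linear fit and falling back to
Levenberg–Marquardt and finally to the flagged log-linear parameters.

## The synthetic generator

Each EMG channel is $\big(e(t)/100\big)\, V_{\mathrm{MVC}}\, c(t) +
\varepsilon(t)$: a stride- or jump-phase-locked envelope $e(t)$ (%MVC)
amplitude-modulating a carrier $c(t)$ — Gaussian white noise band-passed
to 20–400 Hz (zero-phase, 4th-order Butterworth), normalized to unit
mean rectified amplitude per trace — plus white background noise
$\varepsilon$ of SD 0.25 %MVC-equivalent. The normalization makes the
mean rectified amplitude equal the envelope exactly for constant
envelopes, so rectified-mean linearity holds by construction. Stride
envelopes are a tonic level plus two wrapped-Gaussian bursts per cycle
(the biphasic stride-locked pattern of these muscles), with per-muscle
defaults of 0.8–1.5 %MVC tonic and 1.5–5 %MVC bursts, inside the
0.4–6 %MVC range reported for unencumbered running.

Condition effects are per-muscle multipliers scaling the whole envelope;
the shipped defaults are the reported group-mean ratios (e.g.
sternohyoid 3.63 under forward pull, upper trapezius 1.26 under added
head mass; jump conditions at 1.0, the null result for maximal jumps).
The multiplier is applied *exactly* per subject — between-subject
variation enters through MVC amplitude (log-normal, SD 0.2), envelope
scale (SD 0.1), body mass (73.7 ± 7.3 kg) and stride frequency (±5%),
not through the effect itself. Passing recovery tests therefore show
the pipeline is unbiased and correctly plumbed, **not** that it would
attain any particular power at the between-subject effect SDs a real
study reports; the generator likewise omits electrode cross-talk,
motor-unit structure, movement artifacts and amplifier idiosyncrasies
(filtering is parameterized digitally rather than emulating hardware).

Running mechanics: strikes every $1/f_{stride}$ with a triangular foot
transient; two stance pulses per stride ($\sin^2$, duty factor 0.38 of
the cycle) scaled so the per-step mean vertical proper acceleration
matches the per-condition means (9.31 m·s⁻² control); fore-aft waves are
zero-mean sines for control-like conditions (second-half step mean 2.27
m·s⁻²) and one-signed $1-\cos$ waves for pull conditions whose per-step
peaks (forward) or minima (rearward) sit exactly at true zero — i.e. the
generated conditions satisfy the assumptions the baselining rules
encode. The design prints the forward-pull vertical mean with a negative
sign (an axis-orientation artifact); the generator uses magnitudes.
Stride frequency (1.4 Hz) and duty factor (0.38) are not stated by the
design and are set to typical distance-running values; both are
configuration, not claims. A random per-trial sensor offset (SD 0.5
m·s⁻²) is added so baselining is actually exercised.

Jump force curves are piecewise-smooth: quiet standing at $W$, a
$\sin^2$ unweighting dip (depth 0.6 W over 0.35 s), a $\sin^2$ push
(0.30 s), a fast $\cos^2$ drop to zero (0.06 s), flight of duration
$2v_{to}/g$, and a landing spike. The push amplitude is solved so that
the net impulse over the *analysis window* (detected onset to takeoff)
equals the target exactly on the noise-free curve — the window impulse
is affine in the push amplitude, so two evaluations determine it. This
guarantees impulse fidelity and $J = m v_{to}$ consistency by
construction. Default targets are 203.7 / 159.5 / 210.5 N·s (control /
added gravity / added head mass) at the reference 73.7 kg body mass,
scaling with subject mass; the added-gravity condition adds 270 N to
the standing baseline. Submaximal jumps scale the whole envelope by
$e^{b(J - J_{ref})}$ with $b = 0.012$ per N·s, so integrated EMG tracks
$a\,e^{bJ}$ up to a small dependence of the analysis-window length on
effort (larger for the ventral muscles, whose flight burst scales with
flight time; effort-curve recovery is validated on a dorsal muscle).

Two known couplings are worth noting. The MVC reference is the maximum
of a smoothed order statistic and so sits a few percent above the true
100 %MVC amplitude; this biases absolute %MVC values slightly low but
cancels exactly in all condition ratios. And because the added-gravity
jump has a shorter flight, the onset-to-landing window geometry couples
weakly into the maximum-voltage metric (ratios a few percent from 1
under the null, well inside the ±0.05 acceptance band); the family-wise
error-rate property is evaluated on the maximum-voltage metric, whose
null is exact in amplitude.

## Numerical choices and degenerate inputs

Trapezoidal integration at native rate throughout, no resampling; bin
remainders to the earliest bins; centered rolling means with shrinking
edge windows; MAD-based strike threshold ($k = 6$) with a
half-stride-period refractory window resolved largest-peak-first;
Wilcoxon ties mid-ranked, zeros dropped, exact path only without ties;
all-zero difference vectors return $p = 1$ flagged; ratio denominators
$\le 0$ drop the subject from that muscle (logged in the table's `n`);
muscles with fewer than two subjects are flagged untested; a
zero-depth, zero-impulse jump generates a flat trace at standing weight
on which phase detection correctly fails; phase detection failures skip
the trial and are listed in `skipped`, never fatal.

## Problem sizes

The test suite validates unit behaviour on small studies (2–4 subjects,
5–10 cycles) and the end-to-end recovery properties at the full design:
16 subjects × 20 cycles for the running ratio recoveries and 16 subjects
× 4+4 jumps for the null jump study. The family-wise error-rate
simulation uses 200 seeded studies of 8 subjects at 500 Hz — a package
choice trading per-study size for seed count, appropriate because the
Wilcoxon/Holm null behaviour depends on $n$ and $\alpha$, not on the
sampling rate of the underlying traces. `scripts/acceptance.R` runs the
16-subject designs.

## Limitations

The generator's carriers are Gaussian and stationary within the
envelope; real surface EMG is neither, and its amplitude distribution
has heavier tails, so maximum-voltage metrics on real data are noisier
than the synthetic tests suggest. The per-step fore-aft constructions
encode the baselining assumptions exactly; on real data those
assumptions (runner never accelerates forward under forward pull) hold
only approximately, and the resulting offsets inherit that
approximation. No cross-talk, fatigue, or electrode-shift processes are
modelled — the availability mask emulates only the discard-a-bad-
electrode decision. Tilt correction is a scalar cosine for a constant
lean; it does not model within-step orientation changes.
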