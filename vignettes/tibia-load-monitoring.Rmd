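---
title: "Methods: remote tibia bone-load monitoring with insoles and a wrist tracker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: remote tibia bone-load monitoring with insoles and a wrist tracker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After tibia shaft fracture surgery, recovery depends on the bone experiencing
enough mechanical loading to stimulate remodeling, yet clinicians have no
visibility into how patients load the tibia in daily life. Pressure-sensing
insoles can estimate tibia force continuously, but people do not wear shoes
all day: real-world insole wear times of 4--5 h/day leave most of the day's
loading unobserved, and day-to-day wear-time variability makes daily loading
totals incomparable. A wrist fitness tracker, by contrast, is worn nearly all
day but cannot sense bone load directly. `tibload` implements a multi-sensor
pipeline: insole-derived loading wherever insoles were worn, and a trained,
participant-calibrated tracker model to fill the gaps.

## The model chain

**Tibia compression force.** From the insole's total plantar force $F(t)$ and
longitudinal center of pressure $\mathrm{CoP}(t)$ (meters from the back of the
insole), the tibia compression force is the plantar force plus the Achilles
tendon force required to balance the external ankle moment:

$$F_{Tibia}(t) = F(t) + \frac{(\mathrm{CoP}(t) - x)\,F(t)}{r}$$

where $x$ is the measured horizontal distance from the back of the insole to
the ankle joint center and $r$ is the Achilles tendon moment arm, taken
constant at 5 cm. Compression cannot be negative, so the result is clamped at
zero (relevant only at very low loads with the CoP behind the ankle, where
the carried-forward swing-phase CoP makes the moment term meaningless
anyway).

**Loading stimulus (LS).** Bone adaptation responds non-linearly to load
magnitude; following the cumulative-damage literature the per-minute stimulus
is the time integral of tibia force raised to the exponent $m = 4$:

$$LS_j = \int_{t_a}^{t_b} F_{Tibia}(t)^m \, dt, \qquad t_b - t_a = 1\ \text{min}.$$

One minute is the natural epoch because consumer trackers export their
metrics once per minute.

**Daily load stimulus (DLS).** Treating every minute as a discrete loading
task with one cycle, the day summary is

$$DLS = \Big(\sum_j LS_j\Big)^{1/(2m)}.$$

`compute_dls()` refuses incomplete series: a day with missing minutes must be
gap-filled first, which is the package's whole point.

**Units.** The integrand's units are not fixed by the formulas; raw newtons
raised to the 4th power produce astronomically scaled stimuli. `tibload`
normalizes tibia force to bodyweights (BW) before exponentiation, so LS is in
BW$^4\cdot$s and DLS in BW$^{1/2}\cdot$s$^{1/8}$; this keeps magnitudes tame
and participants comparable. A `normalize = "newton"` configuration flag
preserves the raw scale for anyone who wants it. Because LS is homogeneous of
degree $m$ in force (and DLS of degree $1/2$), the choice rescales but never
reorders results.

## Tracker features

Five per-minute features are derived from wrist acceleration magnitude (in g,
gravity included), with the deviation signal defined as $|\,\lVert a\rVert -
1\,|$ — zero at rest, positive in motion:

* **activity time** — seconds with deviation strictly above the 50 mG gate;
* **step count** — device-reported steps (the synthetic cohort emulates a
  counter with a configurable miss rate; no gait algorithm is implemented);
* **activity level** — trapezoidal area under the rectified deviation curve
  (g·s), the "proportional integration" vigor measure;
* **scaled steps / scaled activity** — step count and activity time
  multiplied by the same minute's activity level.

The tracker vendor's exact internal formula is proprietary; this definition
is the package's documented stand-in and is applied identically everywhere,
so models never see a train/serve mismatch.

## Two-stage estimation

**Generic model.** A LASSO regression maps the five features to insole LS,
trained on the pooled minutes of all participants except one and evaluated on
the held-out participant (leave-one-participant-out); `fit_generic()` returns
one model per held-out participant and tags every training row with its
participant so leakage is auditable. Wrist behavior differs between people —
arm-swing amplitude scales the activity level irrespective of tibia load, and
expressive sedentary hand gestures inflate it with no load at all — so the
generic model can fit some participants poorly, to the point of negative
$R^2$.

**Participant calibration.** A second LASSO per participant takes the generic
LS estimate plus the five features, trained only on minutes with simultaneous
insole coverage inside a training window, and re-predicts the rest of the
day. `evaluate_quarter_calibration()` scores the 25%-wear scenario: the day's
covered minutes are split into four contiguous quarters; each quarter trains
a calibration applied to the other three, and pooled held-out predictions are
scored with $R^2$. Quarters are contiguous in time because the scenario being
emulated is a contiguous block of insole wear, not randomly scattered
minutes. Calibration windows whose content is nearly unloaded (fewer than 10
minutes with LS > 0) are flagged `low_information`; predictions from such
windows are known to be unreliable and this is visible in the wear-time
curves below.

**LASSO numerics.** Features are standardized to zero mean and unit variance
on the training rows (constant features get scale 1 and coefficient 0); the
intercept is unpenalized; predictions are clamped at zero since LS is
nonnegative by construction. The penalty is selected by a seeded, explicit
5-fold cross-validation loop minimizing MSE over a fixed grid: 12
log-spaced values spanning three decades below $\lambda_{max}$, plus the
exact unpenalized endpoint. Positive penalties are solved by `glmnet`; the
$\lambda = 0$ endpoint is ordinary least squares and is solved directly by QR
with pivoting (aliased coefficients set to zero), which is both exact and
fast where coordinate descent converges slowly. Ties in CV error resolve to
the larger penalty. The LS target is modeled on its natural BW$^4\cdot$s
scale; a `log1p` option exists behind a config flag but is off by default, as
there is no evidence the original analysis transformed the target. With
fewer rows than folds the fold count drops to the row count (with a
warning); windows too small to cross-validate fall back to the
least-penalized candidate.

## Wear-time simulation

`run_wear_sim()` re-creates partial-wear days from a fully recorded one: a
sliding window marks when the insoles were "worn"; a calibration is fitted
inside the window; minutes outside are filled with its predictions; the
combined DLS is compared with the all-insole reference as an absolute percent
error (APE). Window lengths grow from 30 min in 5-min increments up to the
full day, each length sliding at a stride auto-chosen per day as the largest
stride that still yields at least 300 windows — landing study-like days in
the 300--400 simulated-day band. The simulated day span equals the recorded
span (9--10 h), not a nominal 16-h waking day. Windows that cannot support a
calibration at all (< 2 usable minutes) still produce a simulated day, filled
with uncalibrated generic predictions and flagged, so the very-low-coverage
error inflation remains observable rather than silently dropped. Days whose
reference DLS is below 1e-9 would make percent error meaningless and are
excluded with a warning.

Simulated days are binned by insole coverage into left-open right-closed 5%
bins ((0--5%], (5--10%], ...); APE is averaged per participant per bin, then
across participants (mean and sample SD of the per-participant means). Empty
bins are reported as missing, never zero. Two regimes are expected and
reproduced: above roughly a quarter of the day of insole coverage the
calibrated gap-fill error decays toward zero and sits below the generic
gap-fill curve in every bin; below roughly an hour of coverage the calibrated
curve *inverts* — sparse windows often contain too little loading to
constrain the model, so calibrated error exceeds the flat generic baseline.
Both regimes are asserted in the test suite, with the dominance check applied
from the 25%-coverage operating point upward.

## The synthetic cohort

No public recording of this kind exists, so validation runs on generated
cohorts whose structure embodies what the models assume:

* **Schedule.** Minute-aligned bouts covering a 540--600 min day: mostly
  sedentary, with standing, walking (5--15 min) and occasional vigorous
  bouts, plus two mandatory 20-min "exercise" bouts (morning and afternoon)
  that cycle through moderate/vigorous minutes — a generic stand-in for an
  in-lab rehabilitation battery.
* **Insole stream** (right foot only, 25 Hz). Each step is a half-sine
  vertical-force pulse (walking stance 0.6 s, peak 1.1--1.3 BW; vigorous
  bouts scale the peak by 1.5--2 and quicken the cadence) with the CoP
  progressing linearly heel-to-toe during stance and carried forward
  elsewhere; quiet standing contributes a constant 0.5 BW single-leg force at
  a mid-foot CoP. Per-step amplitudes carry lognormal noise (CV 8%).
* **Ground truth.** The true per-minute LS of the continuous-time trajectory
  is computed by fine midpoint quadrature (2048-point stance shape integrals,
  with straddling steps split at minute boundaries via the cumulative stance
  profile) — independent of the 25 Hz sampling, so the pipeline's trapezoidal
  LS can be checked against it (< 1% discretization error).
* **Wrist stream.** Locomotor minutes carry an arm-swing oscillation whose
  amplitude is scaled by a per-participant lognormal gain (sdlog 0.5);
  sedentary minutes carry ~2-s gesture bursts above the 50 mG gate at a
  per-participant rate (0--6/min); everything else is sub-gate noise. The
  gain spread and the gesture confound are exactly the between-participant
  variability that defeats the generic model, and the dial that controls it:
  zero variance makes generic and calibrated accuracy converge.

What the generator does **not** emulate: biofidelic gait (double support,
loading-rate asymmetries, stairs, slopes), IMU gyroscope channels, clinical
(post-fracture) gait, device clock drift, or multi-day behavior. Passing
tests therefore demonstrate that the pipeline's *mechanics* are correct and
that its qualitative behavior matches the study's under the assumed
statistical structure — not that the numeric error levels transfer to real
patients.

## Problem sizes and determinism

The test suite exercises the default study conditions — 8 participants,
9--10 h days, 25 Hz, 300--400 simulated days per participant — with the
cohort-level properties averaged over 10 generator seeds; component tests use
2--3 participant cohorts with shorter (1--5 h) days, which the generator
supports directly. All randomness flows from explicit seeds through
deterministic child-seed derivation, so `run_study()` is byte-for-byte
reproducible: identical (config, seed) gives identical persisted reports,
and the run log records the config hash and per-stage row counts rather than
timestamps.

## Known limitations

* The Achilles moment-arm model is a single-term moment balance; no muscle
  co-contraction, no joint moments beyond the sagittal CoP lever.
* The 90% minute-coverage rule, the CoP noise-floor carry-forward, and the
  strict 50 mG gate are documented conventions for cases the underlying
  formulas leave open; alternatives would shift minute bookkeeping at the
  margins.
* Whether generic-model training should balance minutes per participant is
  an open question; pooling is unweighted here, so participants with longer
  days carry proportionally more weight.
* Cross-participant spread is reported as the sample SD of per-participant
  values; published spread figures for comparable quantities are ambiguous
  about their convention, so no numeric match is attempted.
* R-squared is undefined for a zero-variance target and raised as an error;
  callers evaluating nearly-unloaded spans will see this early rather than
  receive a misleading score.

## Reproducing the study-scale results

```{r}
library(tibload)
report <- run_study(run_config(), seed = 1)
print(report)
save_report(report, "results/study-seed1")
```

`scripts/acceptance.R --seed 1 --out results/acceptance.json` performs the
same computation and writes the headline quantities (cohort-mean generic and
calibrated R-squared, binned wear-time error summaries) as JSON.
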