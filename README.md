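# tibload

Remote monitoring of tibia bone loading from pressure insoles and a wrist
fitness tracker.

After tibia shaft fracture surgery, bone healing depends on mechanical
loading, but clinicians cannot see how patients load the tibia in daily life.
In-shoe pressure insoles can estimate tibia force continuously — yet people
wear shoes only part of the day, so insole-based daily loading totals are
incomplete and incomparable across days. `tibload` implements a multi-sensor
answer: use the insole where it was worn, and a trained, participant-calibrated
model of wrist-tracker minute metrics to fill the rest of the day.

## The model

From insole total force `F(t)` and longitudinal center of pressure `CoP(t)`
(meters from the back of the insole), tibia compression force adds the
Achilles tendon term balancing the external ankle moment:

    F_Tibia(t) = F(t) + (CoP(t) − x) · F(t) / r

with `x` the back-of-insole-to-ankle distance and `r` the Achilles moment arm
(5 cm). Per minute, the loading stimulus weights load non-linearly
(damage exponent `m = 4`), with force in bodyweights (BW):

    LS_j = ∫ F_Tibia(t)^m dt        over minute j

and the daily load stimulus treats each minute as a discrete loading task:

    DLS = (Σ_j LS_j)^(1/(2m))

A generic LASSO maps five tracker features (activity time, step count,
activity level, scaled steps, scaled activity) to LS, trained and evaluated
leave-one-participant-out; a second, participant-specific calibration LASSO
(generic estimate + the five features, trained on the insole-covered part of
the day) corrects for individual wrist behavior — arm-swing amplitude and
sedentary hand gestures — that defeats the generic model. A sliding-window
wear-time simulation characterizes how the daily (DLS) error grows as insole
coverage shrinks. Because no public dataset of paired day-long insole/tracker
recordings exists, the package ships a synthetic-cohort generator with ground
truth that embodies the statistical structure these models assume.

## Worked example

```r
library(tibload)

# an 8-participant synthetic cohort: 9-10 h days, insole + wrist streams
days <- generate_cohort(cohort_config(), seed = 42)
d    <- days[[1]]

# insole-derived loading stimulus and the all-day reference DLS
ls  <- day_insole_ls(d)
dls <- compute_dls(ls, m = 4)
print(dls)
#> DLS = 4.53543 (m = 4, 577 minutes)

# generic (leave-one-participant-out) and calibrated tracker estimates
models <- fit_generic(days, run_config())
r_squared(ls$ls, predict_generic(models, d)$ls)
#> [1] 0.2269986
evaluate_quarter_calibration(d, models)$r2
#> [1] 0.8560144
```

The DLS (here 4.54 BW^0.5·s^0.125) is the day's cumulative bone-loading
summary: with `m = 4`, doubling every force scales DLS by √2 while doubling
the day's duration scales it only by 2^(1/8) — intensity outweighs duration,
as the damage-weighted exponent intends. The generic model
explains only ~23% of this participant's minute-to-minute LS variance (for
some participants it is worse than predicting the mean, i.e. negative R²),
while a quarter-day calibration raises it to ~0.86 — the package's central
contrast.

The full study pipeline, end to end:

```r
report <- run_study(run_config(), seed = 42)
print(report)
#> tibload study report (seed 42, 8 participants)
#>   generic R^2:    mean -0.807 (sd 2.636)
#>   calibrated R^2: mean +0.704 (sd 0.157)
#>   wear-sim (calibrated): mean APE 33.15% in the (5-10%] bin, 0.01% at full coverage
save_report(report, "results/run42")
```

The binned wear-time curves in `report$bins_calibrated` show the operating
picture: large DLS errors when insoles are "worn" under ~10% of the day
(sparse calibration windows contain too little loading), decaying below 5%
error once roughly a quarter of the day has insole coverage.

A thin command-line front end wraps the same functions:

```sh
exec/tibload simulate-cohort --seed 1 --out cohort/
exec/tibload compute-ls --insole cohort/P01/insole.csv --meta cohort/P01/meta.yaml --out P01_ls.csv
exec/tibload run-study --seed 1 --out results/
```

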