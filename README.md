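# fingertap

Objective scoring of the MDS-UPDRS finger-tapping (FT) task from a
triaxial accelerometer worn on the index fingertip.

Bradykinesia — slowness of movement with decrementing speed/amplitude,
hesitations and halts — is rated clinically by watching the patient tap
index on thumb ten times and assigning a score from 0 (normal) to 4
(cannot perform). The rating is subjective and varies between raters.
`fingertap` implements the full signal-to-score pipeline for researchers
working on wearable-sensor biomarkers of Parkinson's disease:

1. **Epoching** — tap impacts are located as bursts in the level-1
   Daubechies (db4) wavelet detail of the z-axis; the first ten tap-to-tap
   movements are kept, and the opening-acceleration landmark is found
   inside each. Near-flat recordings are immediately flagged score 4 by a
   low-variance rule.
2. **Features** — 18 per-recording features: mean movement frequency
   `Freq` and change-onset indices `Dfreq`/`Afreq` (two consecutive
   significant Welch t-tests over completed-vs-remaining splits), opening
   angle `Angle = asin(a2x) − asin(a1x)` from the x-axis inclinometer and
   its decrement `Dangle`, event counts `Hypom`/`Hesits`/`Halts`, and the
   mean/SD/robust slope of the opening-time fraction and of the peak
   closing/opening accelerations, plus the z RMS.
3. **Model** — proportional-odds ordinal regression,
   `log θ_j = α_j − β₁x₁ − … − β_px_p` with
   `θ_j = P(y ≤ j|x)/P(y > j|x)`, j = 0, 1, 2, fitted by penalized maximum
   likelihood (Newton-Raphson, analytic Hessian, small ridge on β against
   quasi-separation). The continuous severity is `Σ_j j·P(y = j)` in
   [0, 3], discretized at 0.5/1.5/2.5.
4. **Selection & evaluation** — greedy backward wrapper maximizing the
   leave-one-out Goodman-Kruskal Gamma `(C − D)/(C + D)`, and a nested
   (double-loop) leave-one-out evaluation with the 4×4 contingency table,
   Gamma, and ROC/AUC + sensitivity/specificity/accuracy for the three
   binarized tasks (0 | 1–3, 0–1 | 2–3, 0–2 | 3).

No patient data are shipped; a parametric simulator
(`simulate_tap_train()`, `severity_to_params()`, `simulate_cohort()`)
generates severity-graded synthetic recordings with the assumed signal
morphology, so every stage is testable end to end. See the methods
vignette (`vignettes/fingertap-methods.Rmd`) for the model, the simulator's
assumptions, and every numerical choice.

## Worked example

```r
library(fingertap)
set.seed(7)
params <- severity_to_params(2)          # draw a score-2 phenotype
rec <- simulate_tap_train(params, subject_id = "demo")
rec
#> <ft_recording> demo/right: 1340 samples @ 167 Hz (8.02 s)
ep <- epoch_recording(rec)
ep
#> <ft_epochs> 10 movements, taps at samples 51, 175, 299, 423...
round(extract_features(rec, ep), 3)
#>     Freq    Dfreq    Afreq    Angle   Dangle    Hypom   Hesits    Halts
#>    1.347   10.000   10.000   28.180    3.000    0.000    0.000    0.000
#>    Topen  sdTopen  slTopen   Aclose sdAclose slAclose    Aopen  sdAopen
#>    0.381    0.006    0.000    4.393    0.040   -0.008    2.543    0.026
#>  slAopen      RMS
#>    0.002    1.526
```

This draw slowed to 1.35 Hz with a mid-sequence amplitude decrement: the
opening angle has shrunk to 28° and its decrement onset `Dangle = 3` fires,
while the frequency indices stay at 10 (no frequency change) and no
hesitations/halts/hypometria are detected — the mild-slowing/decrement
phenotype of a score-2 hand.

A whole cohort, through selection, fitting, and nested cross-validation:

```r
cohort <- simulate_cohort(rep(0:3, each = 6), seed = 33)
res <- run_pipeline(lapply(cohort, `[[`, "recording"),
                    vapply(cohort, `[[`, integer(1), "latent_score"))
res
#> <ft_pipeline_result> 24 observations (0 excluded as score 4, 0 failed)
#>   global model: Afreq, Dangle, Topen, sdAopen, slAopen, RMS
#>   nested-LOOCV Gamma: 0.934
res$evaluation$tasks
#>    task cut   auc sensitivity specificity accuracy
#> 1 0|123   0 0.991       0.833       1.000    0.958
#> 2 01|23   1 0.944       0.833       0.917    0.875
#> 3 012|3   2 0.861       0.889       0.667    0.833
```

The Gamma of 0.934 says predicted and latent severities are almost
perfectly concordant across the 24 held-out predictions; each `tasks` row
is one binarized screening problem (e.g. row 1: detecting any impairment
vs none).

## Command line

Each stage is also a subcommand (wrapper script in `inst/cli/fingertap`):

```sh
fingertap simulate --score 2 --n 5 --seed 1 --out data/
fingertap epoch    --in data/score2_001.csv --out ep.json
fingertap extract  --in data/score2_001.csv --epochs ep.json --out features.csv --score 2
fingertap fit      --features features.csv --out model.json
fingertap select   --features features.csv --out trace.json
fingertap score    --model model.json --features features.csv --out pred.csv
fingertap evaluate --features features.csv --out report.json
```

All subcommands accept `--config cfg.json` (see `pipeline_config()` /
`write_config()`, which collect every tunable constant with its default),
`--seed`, and `--verbose`; exit status is 0 on success, 2 on validation
errors.

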