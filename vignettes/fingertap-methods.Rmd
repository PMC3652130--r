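---
title: "Methods: accelerometer-based scoring of the finger-tapping task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accelerometer-based scoring of the finger-tapping task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bradykinesia — slowness of voluntary movement with decrement of speed and
amplitude — is the cardinal motor sign of Parkinson's disease. In the
MDS-UPDRS finger-tapping (FT) item the patient taps index on thumb ten
times "as quickly and as big as possible" and a specialist scores each hand
0 (normal) to 4 (cannot perform), judging speed, amplitude, hesitations,
halts and decrement by eye. Such ratings are subjective and show
inter-rater variability. `fingertap` implements an objective pipeline: a
triaxial accelerometer on the index fingertip (±10 g range, 167 Hz),
automatic segmentation of the first ten movements, eighteen movement
features, and an ordinal regression model that predicts the clinical score
and a finer-grained continuous severity.

The package also ships a parametric signal simulator. No patient
recordings are distributed with, or required by, the package: every stage
is exercised on synthetic cohorts whose construction is described below.

## Signal model and simulator

The sensor is mounted with the z-axis perpendicular to the finger (reads
+1 g at the closed, horizontal posture) and the x-axis parallel, so under
quasistatic conditions `x = sin(tilt)` g and the accelerometer doubles as
an inclinometer. The simulator builds each recording from this geometry:

* **Closing burst.** Each tap (index hits thumb) is a 36 ms raised-cosine
  burst with a 50 Hz carrier. The carrier keeps the burst's energy inside
  the level-1 db4 detail band (fs/4 to fs/2 ≈ 42–84 Hz at 167 Hz), which is
  what the tap detector must see. The burst amplitude is `aclose − 1` g so
  the realized raw |z| peak, gravity included, equals the nominal peak
  closing acceleration.
* **Opening bump.** The finger-opening acceleration is a Gaussian bump
  centred at a fraction `topen_frac` of the movement (FWHM ≈ 25 % of the
  movement time). Its amplitude is chosen so that bump + gravity equals the
  nominal `aopen` — amplitudes in this package are raw z readings
  throughout, as in the original method. Hypometric movements replace the
  bump with three narrow sub-bumps of one-third amplitude, emulating the
  fragmented agonist bursts of execution hesitation; this is what makes the
  "> 2 peaks" rule fire.
* **Tilt profile.** Within each movement the tilt rises from 0 (closed) to
  the opening angle and back, with quasistatic plateaus at both extremes
  (~20 % of the movement closed, ~24 % open) so inclinometer windows exist.
  `x = sin(tilt)`, and `cos(tilt)` is added to z as the gravity component.
* **Events.** Hesitations multiply one movement's frequency by 0.66–0.70
  (or 1.30–1.34), or shift its `topen_frac` by 0.16–0.24 — enough to leave
  the ±2 SD outlier band, chosen symmetric so that two events cannot mask
  each other, and small enough never to cross the 0.8 Hz halt threshold.
  Halts subtract 0.9–1.05 Hz from one movement (floored at 0.2 Hz), far
  below the trend. Frequency/angle decrements subtract a step from all
  movements after the onset index.
* **Nuisance.** A 4–6 Hz tremor sinusoid and white Gaussian sensor noise
  (SD 0.02 g) are added to all axes.

Severity draws follow the clinical anchors with uniform parameter ranges
fixed once: score 0 taps at 2.4–3.4 Hz with no events; score 1 draws one of
{1–2 hesitations, slight slowing (1.5–2.0 Hz), late-onset angle decrement};
score 2 one of {3–5 hesitations, mild slowing (1.0–1.5 Hz), mid-sequence
decrement}; score 3 one of {6–8 hesitations, ≥ 1 halt, moderate slowing
(0.8–1.1 Hz), decrement from the first tap}, with reduced amplitudes and
occasional hypometria; score 4 is a near-flat trace (amplitudes of a few
hundredths of a g). Base-frequency ranges decrease and event counts
increase with the score, so the simulated severity gradient is monotone by
construction — the property the ordinal model needs to be learnable.

**What the simulator does not emulate:** biomechanics of a real hand (no
dynamic model behind the waveforms), gyroscope information, realistic
tremor morphology, fatigue within a movement, sensor calibration error, or
the feature correlations of real patients. A green end-to-end test
therefore establishes that the pipeline's machinery is correct and
self-consistent on signals with the assumed morphology — not that the
published clinical performance transfers to any particular cohort.

## Epoching

Taps are located on the absolute level-1 detail reconstruction of the
periodized db4 wavelet transform of z. The original method says only "high
frequency output"; level 1 (the highest band) is fixed here because the
impact burst is the only broadband transient in the signal. The detection
threshold is adaptive, `5 · median(|d|)/0.6745` (a robust noise scale),
with a floor of 15 % of the strongest detail burst — without the floor a
noise-free signal has a near-zero median and arbitrarily small ripples
become "peaks". Peaks closer than 120 ms (an 8 Hz ceiling on tapping) are
merged keeping the stronger.

For tremulous or severely hesitant recordings the original system required
manual adaptation of two windowing parameters; these are exposed as
`window_pos`/`window_width` (seconds). When set, detection anchors at the
strongest burst and searches for each next tap only inside
`[t + window_pos, t + window_pos + window_width]`, which rejects
mid-movement artifacts that pass the amplitude threshold.

A movement is the half-open interval between consecutive taps; only the
first ten are kept. The opening-acceleration landmark is the argmax of the
10 Hz low-passed z inside the movement, excluding an 80 ms guard band around
each tap, after subtracting the gravity baseline `sqrt(1 − x_lp²)`
estimated from the low-passed x-axis (without the subtraction the gravity
modulation, up to ~0.8 g for wide openings, drags the argmax towards the
closed posture).

Recordings whose z variance is below 0.01 g² are flagged score 4 and
excluded from modelling — patients at that level cannot produce a tap
train at all. The rule is monotone in amplitude scaling, and the threshold
sits two orders of magnitude below the variance of the weakest tapping
cohort draws.

## The eighteen features

Per movement: frequency (inverse movement time), opening-time fraction
(landmark position in the movement), peak closing acceleration (max |z| in
a ±50 ms window around the ending tap, raw), peak opening acceleration
(max of the low-passed raw z in the opening phase), and opening angle
`asin(a2x) − asin(a1x)` from the x-axis means over quasistatic windows
(60 ms windows with moving variance < 0.005 g², near the tap for the
closed value and near maximum aperture for the open value; arcsin
arguments clamped to [−1, 1]). Amplitudes stay raw because the gravity
artifact is bounded by `1 − cos(45°) ≈ 0.29` g during the early opening
phase and constant at the closed posture — negligible against the ~9.5 g
feature range.

From these series the feature vector collects means, standard deviations,
robust slopes (IRLS with bisquare weights, tuning constant 4.685, scale
MAD/0.6745), change-onset indices, event counts, and the raw z RMS over
the ten-movement window:

* **Change onset (Dfreq, Afreq, Dangle).** For each split i = 2..8 the
  completed movements 1..i are compared with the remaining ones by a Welch
  two-sided t-test with a directional mean check; if two consecutive
  splits are significant at α = 0.05 the first of them is returned, else
  10. One behaviour of this published rule is worth knowing: when the
  completed side is nearly constant, even heavily mixed splits are
  significant, so on a clean step the rule fires at the first split rather
  than at the step location. The feature still separates "decrement
  present" (small index) from "absent" (10) cleanly, which is what the
  model consumes; the tests pin the rule to an independent brute-force
  enumeration rather than to an intuitive change-point.
* **Halts.** The published rule ("difference between a movement frequency
  and the frequency slope above a threshold") is dimensionally ambiguous;
  it is implemented as trend − frequency > 0.8 Hz, with the trend from the
  robust line — a halt is a movement far *slower* than the trend, so only
  drops count.
* **Hesitations.** A movement counts once if its frequency or its
  opening-time fraction leaves the band trend ± 2 SD of the detrended
  residuals. A halt necessarily leaves the frequency band too, so halted
  movements also count as hesitations; the two features remain separately
  informative because halts use an absolute threshold.
* **Hypometria.** Local maxima of the gravity-compensated, 10 Hz
  low-passed opening segment with prominence above 10 % of the segment
  range; a movement with more than two peaks increments the count.
  Fragmented openings are resolvable only when the movement is slow enough
  for the sub-bursts to be ≥ ~80 ms apart — consistent with the clinical
  presentation, where hypometria accompanies slowed tapping.

## Ordinal model

Scores 0–3 are modelled with the proportional-odds cumulative logit
`P(y ≤ j | x) = logistic(α_j − βᵀx)`, j = 0, 1, 2: one intercept per
cutpoint, shared slopes, and positive β meaning higher feature → higher
severity. Features enter raw (unstandardized), so coefficient magnitudes
must be read against feature ranges. Class probabilities follow by
differencing; the continuous severity is the expectation Σ j·P(y = j), and
discretization uses thresholds 0.5/1.5/2.5 with boundary values rounding
up.

Fitting maximizes the log-likelihood minus `ridge · ‖β‖²` (default
`1e-4`, intercepts unpenalized) by damped Newton-Raphson with the analytic
gradient and Hessian, starting from the empirical cumulative logits. The
likelihood itself acts as a barrier against cutpoint crossing: any step
that would produce a non-positive class probability is rejected by the
step-halving line search, so no explicit reparameterization is needed —
and the exact Hessian is what makes the roughly 10⁵ refits of the nested
wrapper cross-validation affordable. The small default ridge exists
because count features (Halts takes values {0, 1}) can quasi-separate the
classes; at `ridge = 0` the fitter reproduces pure maximum likelihood and
reports separation via the `converged` flag and a diverging coefficient
rather than an error.

Consensus scores from several raters are the rounded mean, with half
values rounding up (the original report does not state the .5 rule; round
half up is the deterministic convention adopted here).

## Feature selection and evaluation

The wrapper starts from all eighteen features and repeatedly removes the
feature whose elimination gives the highest leave-one-out Gamma between
discretized predictions and consensus scores, accepting removals that
leave the criterion unchanged (smaller models preferred) and stopping when
every removal would strictly decrease it. Ties break towards the earliest
feature in the canonical order; subsets are memoized; the whole search is
deterministic given the data.

Performance estimation is a nested leave-one-out: in each outer fold the
wrapper and the model see only the n − 1 training observations — feature
selection inside the loop avoids the optimistic bias of selecting on the
full data — and predict the held-out continuous score. Pooled predictions
yield the 4×4 contingency table, the Goodman-Kruskal Gamma
`(C − D)/(C + D)` over concordant/discordant pairs with ties excluded, and
three binarized tasks (0 vs 1–3, 0–1 vs 2–3, 0–2 vs 3). For
sensitivity/specificity the positive class is the *lower* score group —
the only convention that reproduces the published confusion-table metrics;
one published specificity (0.900 for 0–1 vs 2–3) is inconsistent with the
published table itself, which gives 36/42 ≈ 0.857, and the
table-consistent value is what this package reports. AUC is computed on
the continuous predictions oriented so that higher predicted severity
should accompany higher true severity, with midrank handling of ties
(equals the Mann-Whitney concordance probability).

## Numerical choices and degenerate inputs

* db4 filters: 8-tap Daubechies, periodized transform, perfect
  reconstruction verified against an explicit transform-matrix oracle.
* Low-pass: 4th-order Butterworth (bilinear design), zero-phase by
  forward-backward filtering with odd reflection padding.
* Constant series: robust slope 0 (not an error); change onset 10; all
  t-tests with zero pooled variance return p = 1 on equal means, p = 0
  otherwise.
* Gamma with all pairs tied, metrics with an empty stratum, epoching with
  fewer than two candidate taps: classed errors, never silent NAs.
* Outer folds whose training set misses a class are reported as invalid,
  not dropped silently.

## Limitations

Hardware calibration, video rating, and any claim about real patients are
out of scope. The acceptance checks that involve published numbers operate
on the published contingency table and the closed-form gravity bound; the
cohort-level numbers (Gamma near 0.96, the coefficient table, selection
frequencies) depended on the original 86 observations, which were never
deposited, and are reproduced here in structure only, on synthetic
cohorts.
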