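---
title: "Methods: spine growth reconstruction, spurt alignment and multipliers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spine growth reconstruction, spurt alignment and multipliers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinegrowth)
```

## The problem and the model

Spinal deformity in children progresses fastest during the adolescent
growth spurt, so treatment decisions hinge on how much spinal growth
remains. Chronological age is a poor clock for this: children enter their
spurt at very different ages. This package analyses longitudinal
anthropometric + radiographic data on a *spurt-aligned* time axis and
summarises growth remaining as **multipliers**.

Two definitions anchor everything:

* **PGA₉₀** — the age at which a child first reaches 90% of their adult
  standing height. It is a reproducible surrogate for the timing of peak
  height velocity, which is hard to estimate directly from noisy annual
  measurements. All visits are re-indexed as `timing = age − PGA₉₀`.
* **Multiplier** — adult length divided by current length. A multiplier of
  1.5 means the structure will grow by half again; its reciprocal is the
  fraction of mature size attained. Multipliers remove the need for
  percentile charts: taller and shorter children of equal maturity share
  the same multiplier.

A subject enters the analysis only when growth is complete: standing height
increased by less than 1 cm/yr over the final inter-visit interval. Adult
height is then the final visit's height — not the maximum, which would be
biased upward under measurement noise, and the maturity criterion already
bounds the residual growth below the measurement scale.

## Coordinate conventions

All lengths are centimeters internally (file I/O accepts a declared `mm`
dialect; units are never guessed). Landmark heights are floor-referenced
vertical distances; radiographic offsets are signed with up positive, so
`landmark height + offset` is always the height of the bony structure. A
missing value is an empty CSV cell; a zero height is a validation error,
because 0 cm is never a real measurement.

## The three T1–S1 reconstruction methods

* **Method 1 (direct)**: `T1 = sternal-notch height + notch→T1 offset`,
  `S1 = pelvic-landmark height + landmark→S1 offset`, `T1S1 = T1 − S1`.
  The pelvic landmark is whichever of symphysis, iliac crest or ASIS is
  recorded; when several are available the fixed priority symphysis >
  crest > ASIS keeps runs reproducible. Radiographic offsets are treated as
  directly additive to standing anthropometrics (no supine-vs-standing
  posture correction), which is what the measurement protocol implies.
* **Method 2 (percent C1–S1)**: C1 is approximated as
  `standing height − head height` (head height is vertex to external
  auditory meatus, effectively constant from early childhood);
  `T1S1 = ratio × (C1 − S1)` with ratio 0.762 by default, or the pooled
  cohort median from `estimate_c1s1_ratio()`. The EAM→C1 vertical offset
  (1.7 ± 0.3 cm) is exposed as an optional refinement
  (`apply_eam_offset`), default off, because the base approximation is the
  stated procedure. `estimate_c1s1_ratio()` itself *does* apply the
  recorded offset: a ratio should be taken against the best available C1
  location, and omitting the offset biases the denominator ~1.7 cm low.
* **Method 3 (body regression)**: the through-origin fit
  `body = spine × β̂ + ε` with the closed form `β̂ = Σxy/Σx²`, inverted as
  `spine = body/β̂`. A fitted `β̂` is only meaningful on the scaling
  convention it was fitted under, so the fit carries a convention tag and
  the inversion refuses a mismatch. Note that under a single constant β,
  Method-3 multipliers collapse to standing-height multipliers — the method
  trades per-visit noise for that structural approximation, which is why it
  shows the least scatter and is used as the upper-bound column in
  prediction.

## Locating PGA₉₀

The height series is first made monotone by isotonic regression
(pool-adjacent-violators): a noisy dip would otherwise create multiple
90% crossings. The monotone sequence is interpolated by a monotone
piecewise cubic (Fritsch–Carlson), and the first crossing of
`0.9 × adult height` is bracketed by bisection and polished to numerical
precision, so height at the detected PGA₉₀ equals the target to ~1e-9.
There is no canonical interpolant for locating the crossing; the
isotonic + monotone-cubic choice is declared as this package's own, and on
linear series it reproduces the straight-line crossing exactly.

## Multipliers, the table, and prediction

Per subject and method, adult T1–S1 is the mean of estimates at
timing ≥ 4 (averaging mature visits reduces single-visit noise);
each visit contributes `multiplier = adult/current`. The table bins
observations into half-open half-year bins `[t − 0.25, t + 0.25)` on the
grid −4 … +4.5 — half-open so a boundary observation lands in exactly one
bin. Cells are clamped to ≥ 1, cells at timing ≥ 4 are pinned to 1.000
(the mature definition forces their mean there), and empty cells are
reported missing, never interpolated silently.

`predict_adult_spine()` multiplies the current T1–S1 by the interpolated
multipliers of the two recommended columns — percent-C1–S1 (labelled
lower) and body-height (labelled upper). The columns cross near
timing −0.5, so the numeric bounds are ordered by value while the method
labels are carried alongside. Interpolation is linear between grid cells,
exact at them, 1.0 past the grid, and refuses extrapolation below −4:
early-childhood multipliers are outside the calibrated range.

## Velocities and segmental rates

Phases are fixed half-open timing intervals: childhood (−∞, −2), spurt
[−2, 2), terminal [2, 4), mature [4, ∞). Within each phase, each subject
with ≥ 2 visits contributes an OLS slope of T1–S1 on timing; the summary
reports mean, sem and sd per sex × phase because each cell summarises a
distribution of per-subject slopes. Nothing is clamped on the estimation
side — mature-phase slopes may be negative under noise.

Per-segment rates convert a whole-spine velocity using the segmental
composition of T1–S1 height (thoracic 63% over 12 segments, lumbar 27%
over 5), reported to 0.1 mm with half-away-from-zero rounding. The
arithmetic is reported as computed; it is not forced to agree with any
external per-segment figure.

## Timing vs age: the AVR comparison

To quantify how much better spurt alignment predicts growth remaining than
age does, multiplier curves are fitted both ways: a pooled smoothing
spline against timing, and per-sex splines against age (age curves differ
by sex; timing curves do not). Splines are cubic with smoothing chosen by
generalized cross-validation — on noiseless smooth input GCV drives the
penalty to zero and the residuals to numerical noise. Absolute residuals
(AVRs) are paired by visit and compared with a two-sided paired Wilcoxon
signed-rank test. Because the two models have different predictors, the
result carries an explicit caveat that the comparison is exploratory, not
a formal model comparison.

## The synthetic cohort generator

The generator emulates the structure the analysis assumes, with defaults
fixed to the study conditions the package is calibrated to:

* 35 girls and 19 boys; PGA₉₀ age truncated-normal with mean 11.3 yr on
  (9.7, 13.4) for girls and 13.0 on (11.7, 14.3) for boys; adult standing
  height truncated-normal with mean 163.4 cm on (151, 175) and 177 cm on
  (169, 183.9). Only means and ranges are published for these
  distributions; sd = range/4 is a declared choice, not an inference.
* Adult T1–S1 is 27% of adult height; the subject-level T1–S1/C1–S1 ratio
  is normal (0.762, 0.0176) truncated to (0.70, 0.82). Head height and the
  EAM→C1 offset (1.7 ± 0.3 cm) are drawn once per subject and held
  constant — cranial height matures early.
* The **spine fraction curve** (fraction of adult T1–S1 vs timing) is the
  reciprocal of the reference body-height multiplier column, interpolated
  by a monotone cubic, exactly 1 from the last anchor on, and extended
  linearly below −4 at the first segment's slope. The **height fraction
  curve** is anchored at (−4, 0.79), (−2, 0.85), (0, 0.90), (4.25, 1.0),
  so height at timing 0 is exactly 90% of adult — the PGA₉₀ definition
  closes by construction.
* `trajectory_mode = "piecewise_linear"` replaces the spine fraction curve
  with an exactly piecewise-linear T1–S1 trajectory at the reference phase
  velocities (girls 1.55/1.75/0.9/0.0474 cm/yr; boys 1.14/2/0.881/−0.12,
  negative values clamped to 0 to keep the truth monotone — the −0.12 is
  estimation noise around zero, not shrinkage). This separates estimator
  error from interpolation error in velocity-recovery tests; the
  estimation side still reports negative slopes when it sees them.
* Visits run from 6 yr before to 5.5 yr after the true PGA₉₀ (ages < 3
  dropped), annually, biannually, or mixed (biannual within ±2 yr of the
  spurt — the default, mirroring denser adolescent follow-up).
* Landmark geometry is built top-down so every record is internally
  consistent: C1 sits at `standing − head + EAM offset`; S1 at
  `C1 − C1S1`; T1 at `S1 + T1S1`; the sternal notch and each pelvic
  landmark sit subject-constant offsets from T1 and S1 (notch→T1
  ~N(2.5, 0.5) cm; symphysis→S1 +14, crest→S1 −3, ASIS→S1 −1 cm, sd 1 —
  anatomically plausible values chosen once; the analysis is invariant to
  them because every method adds the same offsets back). Pelvic width
  scales with the spine fraction from an adult width ~N(27, 1.5) cm.
* Measurement noise is independent Gaussian per recorded value: 0.3 cm
  anthropometric, 0.2 cm radiographic. No error magnitudes are published
  for the original instruments; these are package defaults, declared as
  such.
* One global seed fans out to per-subject substreams, so changing the
  cohort size adds subjects without reshuffling existing ones; truncated
  normals are drawn by inverse CDF (one uniform per draw) to keep
  substreams stable.

With all sds zero, every recorded value equals its latent truth: Method 1
reconstructs true T1–S1 exactly; Method 2 is exact when the EAM offset is
applied (without it the approximation is biased by construction, ~1.3 cm,
exactly as in real use); Method 3 reproduces its own fitted values. The
separate `simulate_beta_pairs()` generator provides exactly proportional
(spine, body) pairs for regression recovery, because a single
proportionality constant is not anatomically consistent with the fraction
curves — `body_spine_beta = 1.378` lives there, not in the anatomical
cohort.

### What the generator does *not* emulate

Secular trends; protocol changes mid-series (e.g. switching pelvic
landmarks); sitting-height-specific error structure; posture differences
between supine radiographs and standing anthropometrics; radiographic
magnification and parallax; growth of individual vertebrae or discs;
sagittal alignment. Passing tests therefore demonstrate that the
*estimators* recover the *assumed* structure at the study's scale — they
do not validate the assumed structure against real children.

## Pelvic-width validation

`pelvic_predict()` implements `spine = intercept + slope × width` with a
band of configurable half-width, and `agreement_rate()` reports the
fraction of method estimates inside the band. The published coefficients
for this external check are not reprinted anywhere in this package — a
model must be supplied explicitly, and there is deliberately no silent
default. For synthetic data, `calibrate_pelvic_model()` fits truth on
recorded width and sets the half-width to a residual quantile; with
`estimate_sd` it widens the band in quadrature into a prediction band for
noisy reconstructions, which is the right comparator when checking
estimates rather than truths. The half-width is plain data here, so it can represent
either a pointwise prediction interval or a confidence band, whichever the
supplied external model defines.

## Problem sizes and tolerances used in the tests

The test suite exercises: the study-scale cohort (54 subjects, ~920
visits) for recovery of the −2 and 0 multiplier cells (±0.02), the pooled
ratio median (±0.005) and the AVR ordering; 35-girl and 19-boy
piecewise-linear cohorts for velocity recovery (±0.1 cm/yr on the
childhood and spurt cells — the terminal and mature cells have 2–3 visits
per subject and per-subject sds near 1 cm/yr, so their cell means are not
recoverable to 0.1 at this cohort size, a property the published sds
themselves imply); 500 calibration pairs for β̂ (±0.005); 10,000
truncated-normal draws against the closed-form truncated mean (3
Monte-Carlo SEs); a 200-subject cohort for PGA₉₀ error under noise
(median < 0.2 yr); and noise-free biannual cohorts for exact pipeline
closure (< 0.01 on fractions, < 0.02 cm/yr on slopes).

## Known limitations

* The multiplier grid stops at −4 yr; early-childhood prediction is out of
  calibrated range and is refused rather than extrapolated.
* Method 3's β̂ is scaling-convention-bound; the 1.378 constant is
  dimensionally opaque when both spans are in cm (163.4/1.378 ≈ 118.6 cm
  is no anatomical spine span), which is why the package enforces
  fit/inversion convention consistency instead of guessing a unit.
* The maturity criterion uses only the final inter-visit interval, exactly
  as stated; under heavy noise a truly mature subject can fail it (~10% of
  default-noise subjects), an attrition pattern real longitudinal growth
  cohorts show when selecting subjects whose growth has demonstrably
  finished.
* Subjects failing maturity, or whose first visit is already past 90% of
  adult height, are excluded from multiplier and velocity estimation.
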