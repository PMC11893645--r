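# spinegrowth

Longitudinal analysis of spinal height growth in children, and prediction of
adult spine height from a child's current measurements.

Predicting how much growth the spine has left is central to timing
growth-modifying treatment of pediatric spinal deformity: deformity
progresses fastest during the adolescent growth spurt, and the spurt happens
at different ages in different children. `spinegrowth` implements a complete
pipeline for serial anthropometric + radiographic cohorts that

1. reconstructs per-visit **T1–S1 spine height** (top of the first thoracic
   vertebra to the top of the sacrum) by three complementary methods,
2. aligns every child on their **growth-spurt timing** rather than their age
   — the spurt peak is located as the age at 90% of adult standing height
   (**PGA₉₀**),
3. derives **growth-remaining multipliers** (adult length ÷ current length)
   on a half-year timing grid, **phase-wise growth velocities** and
   per-vertebral-segment rates, and
4. predicts adult T1–S1 height with method-based lower/upper bounds.

Because serial radiographic studies of healthy children can no longer be
collected, the package ships a calibrated **synthetic cohort generator**
that emulates the measurement structure of such a study (latent spurt
timing, fraction-of-adult growth curves, geometrically consistent landmark
heights and radiographic offsets, measurement noise), so the whole pipeline
is testable end to end against known ground truth.

## The model in brief

For subject *i* at visit *j*, let `H_ij` be standing height and `S_ij` a
spine span. With `A_i` the adult value, the **multiplier** at spurt-relative
timing `t = age − PGA₉₀` is

```
m(t) = A_i / S_ij ,    1/m(t) = fraction of mature length attained
```

The three reconstruction methods are:

* **direct** — T1 height (sternal-notch height + radiographic notch→T1
  offset) minus S1 height (pelvic-landmark height + landmark→S1 offset);
* **c1s1_fraction** — T1–S1 as a fixed fraction (median 76.2%) of the C1–S1
  span, with C1 approximated as standing height − head height (vertex to
  external auditory meatus), optionally refined by the EAM→C1 offset
  (1.7 cm);
* **body_regression** — the through-origin fit `H_ij = S_ij · β̂ + ε_ij`,
  `β̂ = Σxy/Σx²`, inverted as `S = H/β̂`.

Growth phases are fixed timing intervals: childhood (< −2 yr), spurt
(−2 to +2), terminal (+2 to +4), maturity (≥ +4); per-subject OLS slopes of
T1–S1 within each phase give the velocity table (mean, sem, sd by sex).

## Worked example

Simulate the default study-scale cohort (35 girls, 19 boys) and run the full
pipeline:

```r
library(spinegrowth)
res <- run_pipeline(generator = generator_config(seed = 1))

dplyr::filter(res$multiplier_table, method == "direct",
              timing_yr %in% c(-2, 0, 2, 4))
#>   timing_yr method multiplier     sd     n
#> 1        -2 direct       1.27 0.0205    46
#> 2         0 direct       1.15 0.0176    46
#> 3         2 direct       1.04 0.0137    46
#> 4         4 direct       1    0.0118    46
```

Two years before the spurt peak the spine still has ~27% growth remaining
(multiplier 1.27); at the peak ~15%; by four years after, growth is
complete (multiplier pinned at 1). The recovered cells match the reference
multiplier table (`multiplier_reference()`) the generator is calibrated to:
1.274 at −2 and 1.148 at 0.

```r
res$ratio$median            # pooled T1-S1/C1-S1 ratio across 782 visits
#> [1] 0.7573

print(res$avr)
#> AVR comparison (paired Wilcoxon signed-rank, n = 782)
#>   median AVR vs timing: 0.0109
#>   median AVR vs age:    0.0225
#>   two-sided p: <2e-16
```

The residuals around the multiplier-vs-timing curve are half the size of the
residuals around the multiplier-vs-age curves: spurt alignment predicts
growth remaining far better than chronological age.

Predict an adult spine height from a single visit — a child with T1–S1 of
38 cm at their spurt peak:

```r
predict_adult_spine(38, timing_yr = 0)
#>   current_t1s1 timing_yr predicted lower upper lower_method upper_method
#> 1           38         0      43.9  43.6  44.1 body_height  pct_c1s1
```

## Learn more

The methods vignette (`vignettes/spine-growth-methods.Rmd`) documents the
model assumptions, the generator's calibration and its limitations, and the
numerical choices (isotonic pre-smoothing, interpolation, binning,
tie-breaking) in detail.
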