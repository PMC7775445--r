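# saliencecpt

Simulation and ERP analysis of the **Salience Continuous Performance
Task** (Salience CPT): a 'not-X' Go/NoGo letter task extended with rare,
physically salient Go stimuli (red squares).  The package is aimed at
cognitive-neurophysiology researchers who quantify inhibition- and
salience-related ERP components — and their trial-to-trial variability —
and relate them to a continuous ADHD index in pediatric cohorts.  Since
no participant data are publicly deposited for this paradigm, the
package ships a synthetic-cohort generator with injected ground-truth
effects, so the complete pipeline (task design → EEG epochs → behavioral
responses → preprocessing → component measures → correlation battery) is
testable end to end.

## What it computes

For a component window (electrode *e*, interval *[t₀, t₁]*, polarity
*p*) on a waveform *w(t)* (a condition average or difference wave, e.g.
inhibition: NoGo − StandardGo; salience: SalientGo − StandardGo):

* **Signed-area amplitude** (µV·ms):
  *A = ∫ₜ₀ᵗ¹ max(p·w(t), 0) dt*, reported as a positive magnitude
  (trapezoid rule on the 200 Hz grid).
* **50% fractional-area latency** (ms): the smallest *t* with
  cumulative rectified area *= 0.5·A*, solved exactly on the
  piecewise-linear waveform.
* **Temporal variability**: the SD of these two measures across the
  single trials of the critical condition.
* **Behavioral metrics**: HIT/MISS/FA/CorrectInhibition classification
  under the 200–1500 ms response window, commission ratio
  FA/(FA + CorrectInhibition), omission ratio MISS/(MISS + HIT), HIT-RT
  means/SDs, and the salience RT effect.
* **Correlation battery**: per measure, single-pass 3-SD outlier
  exclusion, a Shapiro–Wilk gate choosing Pearson vs Spearman, partial
  correlation controlling age/sex/IQ (df = n − 2 − k), significance at
  α = 0.05 and at the Bonferroni threshold α/4 = 0.0125, plus
  manipulation-check t-tests, extreme-group (tercile) contrasts,
  polynomial R² fits, and the Fisher-z minimum detectable correlation
  *r = tanh((z₁₋α/₂ + z_power)/√(n−3))*.

The design defaults are the published ones: 8 × 100 trials (25% NoGo,
10% SalientGo per block, 1650 ms trial duration); inhibition-P3 at POz
300–600 ms, salience-P3 at POz 350–600 ms (Pz replications), salience-N2
at Fz 250–350 ms.

## Worked example

```r
library(saliencecpt)

seqn <- generate_sequence(cpt_task_params(), seed = 1)
seqn
#> Salience CPT trial sequence
#>   800 trials in 8 blocks (100 per block), trial duration 1650 ms
#>   composition: NoGo=200, SalientGo=80, StandardGo=520

prof <- simulate_profiles(31, effect_config(), seed = 1)
row <- measure_subject(prof[1, ], seed = 101)
round(unlist(row[c("inhibition_P3_POz_amp", "inhibition_P3_POz_lat",
                   "inhibition_P3_POz_amp_sd", "inhibition_P3_POz_lat_sd",
                   "salience_N2_Fz_amp", "commission_ratio",
                   "salience_rt_effect")]), 2)
#>    inhibition_P3_POz_amp    inhibition_P3_POz_lat inhibition_P3_POz_amp_sd
#>                  1126.78                   467.67                   268.97
#> inhibition_P3_POz_lat_sd       salience_N2_Fz_amp         commission_ratio
#>                    24.47                   101.33                     0.32
#>       salience_rt_effect
#>                    58.67
```

This subject's inhibition-P3 has a signed area of ≈1127 µV·ms peaking
near 468 ms (trial-wise SDs ≈269 µV·ms and ≈24 ms), a salience-N2 area
of ≈101 µV·ms, a commission-error rate of 32% on NoGo trials, and
responds ≈59 ms slower to salient than to standard Go stimuli.

A full cohort run — simulate, measure, and analyze 31 subjects, writing
TSV tables and a reproducibility manifest:

```r
run <- run_pipeline(cpt_config(n_subjects = 31, seed = 1,
                               out_dir = "demo_run"))
run
#> Salience CPT pipeline run: 31 subjects
#>   battery rows: 20  ( 8 Bonferroni-significant )

b <- run$battery
b[b$component == "salience_P3" & b$site == "POz",
  c("measure", "method", "coefficient", "p")]
#>    measure   method coefficient       p
#> 3      amp spearman       -0.49 0.00757
#> 8      lat spearman        0.63 0.00031
#> 13  amp_sd spearman       -0.63 0.00029
#> 18  lat_sd spearman        0.51 0.00602
```

Here the default injected effects are visible at n = 31: higher ADHD
index goes with smaller salience-P3 amplitude and larger amplitude- and
latency-variability (signs as injected; at this cohort size individual
coefficients scatter widely around their targets — the power bound below
is the reason).

```r
round(min_detectable_r(31), 2)
#> [1] 0.48
```

Only correlations above ≈0.48 are detectable with 80% power in a sample
of 31 — the design-level constraint under which the correlation battery
operates.

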