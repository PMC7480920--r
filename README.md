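# trialpower

Which longitudinal biomarker powers a clinical trial of early Alzheimer's
disease most efficiently? Plasma neurofilament light (pNfL) is cheap to
sample often; MRI composites change fast and cleanly but are sampled
rarely; cognitive composites are the regulatory standard but noisy.
`trialpower` turns longitudinal observational data into that comparison:
it builds diagnostic groups from visit tables, fits a random-slope linear
mixed model per biomarker and group, converts the fit into the per-arm
sample size required to detect a fractional slowing of progression, sweeps
trial duration and sampling frequency, and bootstraps the between-biomarker
differences.

## The model and the formula

Each biomarker in each group follows a linear mixed model over time in
years,

    y_ij = b0 + b1*t_ij + b0_i + b1_i*t_ij + e_ij,

fitted by REML (`nlme`), giving the group slope `b1`, the within-subject
variance `sigma_w^2`, and the between-subject slope variance `sigma_b^2`.
For a two-arm trial with visits `t_1..t_J`, two-sided level `alpha` and
target power `1 - beta`, the subjects needed per arm to detect a slope
difference `Delta` are

    n = 2 * (sigma_b^2 + sigma_w^2 / sum_j (t_j - t_bar)^2)
          * (z_{1-alpha/2} + z_{1-beta})^2 / Delta^2

with `Delta` a fraction (default 30%) of either the group slope
("full" mechanism: treatment can stop progression) or the group-minus-
control slope ("disease-specific": treatment can at best restore normal
aging). The `sum (t_j - t_bar)^2` term is how duration and sampling
frequency enter: denser or longer sampling suppresses only the
within-subject noise term, which is why frequent blood draws help pNfL
but cannot shrink slope heterogeneity. A Monte-Carlo simulator
(`mc_power_validate()`) and a subject-level bootstrap quantify,
respectively, the formula's accuracy and the estimate's uncertainty. A
bundled synthetic-cohort generator with the same mixed-model structure
(ADNI-like visit grid, monotone dropout, per-modality missingness) makes
the whole pipeline runnable and testable without access-restricted data.

## Worked example

A single design evaluation — 30-month trial, quarterly assessments, a
biomarker progressing at 0.2 sd/year with `sigma_w^2 = 0.3`,
`sigma_b^2 = 0.01`, detecting a 30% slowing (`Delta = 0.06` sd/year):

```r
library(trialpower)
sch <- build_schedule(30, 3)
n_per_arm(sigma_w_sq = 0.3, sigma_b_sq = 0.01, schedule = sch, delta = 0.06)
#> Per-arm sample size: 234 (continuous 233.88)
#>   sigma_w^2 = 0.3, sigma_b^2 = 0.01, delta = 0.06 /yr
#>   alpha = 0.05 (two-sided), power = 0.8, 11 visits, ssq = 6.875 yr^2
```

234 participants per arm; `power_at_n(233.88, ...)` returns the 0.80
target exactly. The full pipeline on a synthetic cohort (three diagnostic
groups, five biomarkers, default designs: 30-month preclinical trial with
monthly pNfL and quarterly MRI/cognition, 18-month mild-AD trial):

```r
cfg <- run_config(synth = list(n_control = 120, n_preclinical = 120,
                               n_mild = 120),
                  contrasts = FALSE, seed = 42)
run <- run_analysis(cfg)
#> input: 360 subjects, 2034 visit rows
#> cohort: 293 eligible of 360 (control 99, preclinical 103, mild 91)
#> fits: 15 biomarker x group models, 0 failed or non-converged
run
#> trialpower run (config 52c10da4 )
#>             group   biomarker duration frequency n_per_arm
#> 1  preclinical_ad        pnfl       30         1        93
#> 2  preclinical_ad    temporal       30         3        52
#> 3  preclinical_ad hippocampus       30         3        27
#> 4  preclinical_ad       cdrsb       30         3      1193
#> 5  preclinical_ad        pacc       30         3      1167
#> 6         mild_ad        pnfl       18         1       359
#> 7         mild_ad    temporal       18         3        29
#> 8         mild_ad hippocampus       18         3        15
#> 9         mild_ad       cdrsb       18         3        94
#> 10        mild_ad        pacc       18         3       137
```

Read: under the generator's default parameters the MRI measures need the
fewest subjects in both groups (hippocampal volume 27 per arm in the
preclinical design), pNfL sits in between despite monthly sampling, and
the cognitive composites are weakest in the preclinical group where
cognition barely changes. These numbers characterize the method on
synthetic defaults, not any real cohort. `run_sensitivity()` re-runs the
pipeline under overlapping-visits, tau-positive, or low-frequency
variants, and `sweep_designs()` maps how the comparison shifts with
duration and sampling frequency.

A thin command-line wrapper for cohort generation and pipeline runs is
included at `inst/scripts/trialpower.R`.

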