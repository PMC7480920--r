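---
title: "Comparing longitudinal biomarkers as trial outcome measures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing longitudinal biomarkers as trial outcome measures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(trialpower)
```

## The question

A disease-modifying trial in early Alzheimer's disease must choose an
outcome measure: plasma neurofilament light (pNfL), an MRI volumetric or
thickness composite, or a cognitive composite. Each progresses at a
different rate and with different noise structure, so each implies a
different number of participants for the same target power. This package
turns longitudinal observational data into that comparison: it fits a
linear mixed model per biomarker and diagnostic group, plugs the fitted
slope and variance components into a closed-form sample-size formula for
slope contrasts, and quantifies the uncertainty of the comparison by
subject-level bootstrap.

## The longitudinal model

For subject $i$ at time $t_{ij}$ (years from baseline), each biomarker is
modelled as

$$ y_{ij} = \beta_0 + \beta_1 t_{ij} + b_{0i} + b_{1i} t_{ij} +
\varepsilon_{ij}, \qquad (b_{0i}, b_{1i}) \sim N(0, \Sigma), \quad
\varepsilon_{ij} \sim N(0, \sigma_w^2), $$

fitted by REML with `nlme::lme` and an unstructured $2 \times 2$
random-effect covariance. Three quantities feed the power analysis:

* $\beta_1$ — the group-average progression slope (sd/year after
  standardization);
* $\sigma_w^2$ — the within-subject variance, how much one person's
  points scatter around their own line;
* $\sigma_b^2 = \mathrm{Var}(b_{1i})$ — the between-subject variance of
  individual slopes. Only the slope component enters the power formula;
  intercept heterogeneity is absorbed by the subject-specific intercepts.

Models occasionally fail on noisy biomarkers. `fit_slope_model()` walks a
fallback ladder — unstructured covariance under two optimizers, diagonal
covariance, then random intercept only ($\sigma_b^2 = 0$) — and records
which rung succeeded in the `method` tag. If every rung fails, per-subject
OLS moment estimates are returned flagged `converged = FALSE`, and all
downstream operations refuse such fits unless forced; failed fits are
reported, never silently dropped. Exactly collinear data (every subject on
a line, identical slopes) would make the mixed model unidentifiable, so
this degenerate case is detected up front and returned as an exact moment
fit.

## The sample-size formula

With visit schedule $t_1, \dots, t_J$ the per-arm sample size to detect a
slope difference $\Delta$ with two-sided level $\alpha$ and power
$1 - \beta$ is

$$ n = \frac{2 \left( \sigma_b^2 + \sigma_w^2 / \sum_j (t_j - \bar t)^2
\right) (z_{1-\alpha/2} + z_{1-\beta})^2}{\Delta^2}. $$

The bracket is the sampling variance of one subject's estimated slope, so
this is the classical two-sample normal formula applied to subject-level
slopes. The $\sum_j (t_j - \bar t)^2$ term is where trial duration and
sampling frequency enter: longer trials and denser sampling shrink only
the $\sigma_w^2$ contribution, which is why high-frequency blood sampling
helps a noisy marker like pNfL but cannot reduce between-subject slope
heterogeneity.

$\Delta$ encodes the assumed treatment mechanism as a fraction $f$
(default 30%) of the relevant progression:

* **full** — therapy can abolish progression: $\Delta = f\,|\beta_1|$ of
  the treatment group;
* **disease-specific** — therapy can at best restore normal-aging rates:
  $\Delta = f\,|\beta_1^{grp} - \beta_1^{ctrl}|$.

`power_at_n()` inverts the formula using the dominant-tail normal
approximation $\Phi(\Delta\sqrt{n/(2v)} - z_{1-\alpha/2})$; the neglected
opposite tail is below $10^{-6}$ in any regime where a trial would be run.
The round trip `power_at_n(n_per_arm(...)$n_continuous, ...)` returns the
target power to $10^{-9}$.

```{r}
sch <- build_schedule(18, 6)        # months 0, 6, 12, 18 -> years
n_per_arm(sigma_w_sq = 1.0, sigma_b_sq = 0.1, schedule = sch, delta = 0.3)
```

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `effect_fraction` | 0.30 | — | conventional assumed slowing of progression |
| `alpha` | 0.05 | — | two-sided test level |
| `power` | 0.80 | — | target power |
| duration | 30 (preclinical), 18 (mild) | months | typical phase-III exposure at each stage |
| frequency | 1 (pNfL), 3 (MRI, cognition) | months | monthly infusion visits make monthly blood draws feasible; imaging/cognition every 3 months |
| SUVR intercept cutoff | 0.79 | — | published amyloid-PET positivity threshold (strict `>`) |
| CSF A$\beta$42 cutoff | 880 | pg/mL | published Elecsys threshold (strict `<`) |
| CSF P-tau181 cutoff | 27 | pg/mL | published threshold (strict `>`) |
| `B` | 250 | — | bootstrap iterations |
| overlap tolerance | 1.5 | months | half-window for matching off-schedule visits |

Boundary conventions are strict inequalities throughout; only the PET
cutoff's direction is stated in the source literature as ">", and the
other two were made strict for consistency. Equal values at a cutoff are
vanishingly rare in continuous assays, so the choice is inconsequential in
practice.

Time is in months at every interface (visit tables, designs) and is
converted to years inside model fitting, so slopes and slope variances are
per-year quantities.

## Standardization

Slopes are comparable across biomarkers only on a common scale. Each
biomarker is z-scored against the pooled baseline observations of all
eligible subjects (all three groups), so every slope reads as
"baseline-SDs per year". A control-only reference was the plausible
alternative; pooled baseline was chosen because it keeps the scale defined
even for measures that barely vary in controls (e.g. CDR Sum-of-Boxes)
and standardizes all groups with one set of statistics. pNfL enters
untransformed (no log) before z-scoring; the reference statistics are
recorded with the data for provenance, and re-standardizing an already
standardized table is the identity.

The cognitive composite is the *sum* (not mean) of the four oriented
z-scores, with the Trail-Making B completion time sign-flipped so higher
is always better; a visit missing any component yields a missing composite
rather than a pro-rated one, since an "equally weighted sum" is
ill-defined under partial data. The temporal cortical composite is the
surface-area-weighted mean thickness over the bilateral entorhinal,
fusiform, inferior and middle temporal regions.

## Cohort construction

Amyloid status anchors group membership. Because many subjects lack PET at
the common baseline, each subject's longitudinal SUVR series is regressed
on time and the intercept (estimated SUVR at baseline) is thresholded;
subjects without any PET fall back to CSF A$\beta$42. Groups are then:
controls (amyloid-negative, CDR 0), preclinical AD (amyloid-positive,
CDR 0), mild AD (amyloid-positive, CDR 0.5–1); everything else is
excluded with an explicit reason.

Eligibility requires at least two *post-baseline* observations in each of
the three modalities (plasma, MRI, cognition). "At least two follow-up
measures" could arguably count baseline; the post-baseline reading was
chosen because a slope model needs within-subject time spread beyond the
anchor visit, and the interpretation is a single argument
(`min_followups`) if a user disagrees.

The overlapping-visits sensitivity analysis (`run_sensitivity(...,
"overlapping_visits")`) snaps each modality's observations to the nearest
nominal visit within ±1.5 months and keeps only visits where all three
modalities coincide — the guard against one modality's richer follow-up
schedule flattering its variance estimates.

## The synthetic cohort generator

`generate_cohort()` draws subjects from exactly the generative model the
analysis assumes: per (group, biomarker) a bivariate-normal random
intercept and slope, a linear mean trajectory, and i.i.d. Gaussian
within-subject noise, on the 0/6/12/24/36/48/60-month observational visit
grid with monotone dropout (retention declining to 55% by month 60) and
independent per-modality missingness. Plasma NfL is collected annually
from month 12 (no month-6 draw), amyloid PET every two years, CSF at
baseline only. Auxiliary variables (CDR, SUVR, CSF) are group-conditioned
draws placed well clear of the classification cutoffs, so the cohort
builder recovers the intended labels for ≥99% of subjects — their realism
beyond that is a non-goal.

The default parameter table is illustrative, not an estimate from any real
cohort: the source material reports the variance decomposition only
graphically. The defaults are pinned down by the reported qualitative
structure — pNfL has the highest within-subject noise and the smallest
between-subject slope variability; MRI composites progress faster than
pNfL in disease groups; disease slopes exceed control slopes everywhere;
and the pNfL slope gaps versus controls are fixed at 0.04 sd/year
(preclinical) and 0.06 sd/year (mild), the two reported contrasts. Group
sizes default to 330/218/697 (control/preclinical/mild). These choices
were made once, from those constraints, and are not tuned.

Reproducibility: one root seed; each subject's stream is derived
deterministically from (seed, subject index), so the same seed gives a
bit-identical cohort regardless of generation order.

What passing tests on this generator do *not* show: real trajectories are
not exactly linear (floor/ceiling effects in cognition, practice effects),
dropout is informative in real cohorts, assay batch effects exist, and
real variance components differ from the illustrative defaults. The
generator validates the *machinery* — estimation, formula, bootstrap — not
any substantive claim about which biomarker wins on real data.

## Monte-Carlo validation and the bootstrap

`mc_power_validate()` is the independent check on the closed form: it
simulates complete two-arm trials observation by observation, summarizes
each subject by the OLS slope of their own series, and applies the
two-sided Wald z test to the arm difference. For balanced complete data
this is numerically the same test as the time-by-arm Wald test in the
random-slope LME, at a small fraction of the cost; an `engine = "lme"`
option fits the full `nlme` interaction model per trial and is checked
against the fast path in the test suite. Empirical power at the computed
`n_per_arm` lands within ±3 percentage points of the 80% target across
random parameter draws, and at `f = 0` the rejection rate sits at the
nominal 5%.

Uncertainty in the required `n` comes from a subject-level bootstrap
(resample subjects with replacement, refit, recompute `n`), with
percentile 95% intervals — "standard bootstrapping" with no further
qualification is read as percentile, not BCa. Between-biomarker
comparisons resample *paired*: one subject draw per replicate is used for
both biomarkers, and the two-sided p-value is
$2\min(\#\{d \le 0\} + 1, \#\{d \ge 0\} + 1)/(B+1)$, capped at 1; the
add-one correction keeps p strictly positive with floor $2/(B+1)$, so
"p < 0.0001"-style statements require large $B$. $B$ defaults to 250 (the
stated procedure), with 100 (the figure-legend value in the source; which
produced the printed intervals is unknowable) one argument away. Under the
disease-specific mechanism the control fit is recomputed inside every
replicate from a paired control resample, so control-slope uncertainty
propagates. Non-converged replicates are recorded and dropped from the
percentiles; a result with >50% failures is flagged unusable. Bootstrap
statistics are summarized on the continuous `n` to avoid ceiling-induced
ties.

## Numerical conventions

* Schedules always include baseline ($t = 0$) and count it as an
  assessment. When the duration is not a multiple of the frequency the
  grid truncates at the last attainable visit; `anchor_end = TRUE` forces
  a final visit at the duration itself.
* `n_per_arm` is the ceiling of the continuous solution, never below 1.
* $\Delta$ enters as a magnitude. A disease-specific contrast whose sign
  opposes the group slope (disease progressing *slower* than controls)
  warns rather than errors — the formula still answers the question asked.
* A slope of exactly zero is reported as an explicit "unpowered" error,
  not as numerical overflow.
* Sweep grids (`sweep_designs()`) report each biomarker's `n` against the
  reference biomarker at the same duration with the reference held at its
  own fixed frequency; ratio $> 1$ means the biomarker needs fewer
  subjects than the reference. Per-cell failures carry `NA` and the error
  message; one failing cell never aborts the grid.
* Wald tests use the normal approximation throughout, matching the
  z-quantiles in the sample-size formula.

## Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to balance statistical
resolution against desk-scale runtime: parameter recovery uses 200
replicates of 500 subjects × 7 visits; the Monte-Carlo oracle 20 parameter
sets × 2,000 simulated trials; bootstrap coverage 50 outer replications of
120-subject cohorts with $B = 100$; the end-to-end ordering check runs the
full default cohort (330/218/697). Tolerances follow from the binomial or
sampling error at those sizes (e.g. ±3 points at 2,000 simulations is
about 3.3 binomial SEs).

## Known limitations

* The formula assumes complete data over the schedule; no dropout
  inflation is applied by default (a multiplicative retention adjustment
  is deliberately left to the user, since the formula itself has no
  dropout term).
* Linear trajectories only; no practice effects, no nonlinear or
  change-point progression, no informative dropout.
* Equal allocation, fixed design — no group-sequential or adaptive
  features.
* No multiplicity adjustment across the biomarker family (none is applied
  in the source analysis either).
* The required-n numbers printed from synthetic defaults are illustrative
  of the *method*; they are not estimates for any real cohort, and the
  headline numbers from the restricted source cohort are not reproducible
  here by design.
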