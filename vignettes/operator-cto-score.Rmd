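---
title: "The operator-CTO score: model, synthetic cohorts, and evaluation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The operator-CTO score: model, synthetic cohorts, and evaluation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctoscore)
```

## The scoring model

Percutaneous coronary intervention of a chronic total occlusion (CTO-PCI)
succeeds or fails on two things: how hostile the lesion is, and who is
holding the wire. Classical additive difficulty scores (J-CTO, PROGRESS,
ORA, RECHARGE, CL) quantify only the first. The operator-CTO score adds the
second as negative "credits", so the same lesion is graded easier in more
experienced hands.

The score is a plain sum of indicator variables — no fitted weights:

* **+1 each** for nine adverse case variables: prior bypass surgery on the
  target vessel; blunt (knife-cut) proximal stump; any calcification of the
  occluded entrance or body; severe angulation (at least two bends over 70
  degrees or one over 90 in the occluded segment); occlusion length **>= 20
  mm**; distal vessel disease (significant disease beyond the occlusion
  and/or distal lumen under 2 mm); collateral Rentrop grade **< 2**;
  in-stent occlusion; ostial location.
* **-1** for annual CTO-PCI volume >= 60 cases, **-1** for >= 5 years as
  lead CTO-PCI operator, **-2** for a last-year technical success rate
  >= 90 %.

The total lies in [-4, 9] and maps to four procedural difficulty tiers:
simple (<= 2), medium (3), difficult (4), extremely difficult (>= 5).
`classify_difficulty()` enforces the range; all threshold comparisons are
implemented with exactly the printed inclusive/strict boundaries and no
tolerance — a last-year rate of 0.8999 earns no credit.

Two boundary subtleties are deliberate and tested:

* the operator-CTO length variable fires at **>= 20 mm**, while J-CTO,
  RECHARGE and CL use **> 20 mm**; the two differ only at exactly 20 mm.
  Under the continuous length distribution of the generator the difference
  has probability zero, but for hand-entered data it matters.
* only CL distinguishes *severe* calcification (2 points) from any
  calcification; the case table therefore carries both `calcification` and
  `calcification_severe`, with the implication `severe => any` validated on
  construction. Tortuosity is likewise stored as two implied booleans
  (`bend_ge45` for the 45-degree rule of J-CTO/RECHARGE,
  `severe_angulation` for the stricter PROGRESS-style rule) because the
  scores are defined by threshold rules, not raw angles. The ostial-location
  variable is a single field shared by the ORA and operator-CTO scores.

Operators fall into experience groups I-V from the same three thresholds
(years, volume, rate). The five named groups do not cover all eight
combinations; a sub-threshold operator with a >= 90 % success rate is
resolved by the success-rate criterion first (into group V) and flagged,
since the rate carries the largest credit and the unlisted combinations are
rare in practice.

## What the synthetic cohort emulates

No patient-level data ship with the package. `generate_cohort()` builds
cohorts with the *marginal* structure of a 144-procedure single-centre
registry:

* **Feature prevalences** (defaults): blunt stump 0.576, calcification
  0.333, curvature 0.910, length >= 20 mm 0.882, distal disease 0.542,
  ostial 0.479, in-stent 0.139, Rentrop < 2 0.319, prior MI 0.308, prior
  target-vessel CABG 1/144; target vessel LAD/LCX/RCA/LM at
  0.424/0.097/0.472/0.007. One source table and its narrative swap the
  calcification and curvature percentages; the defaults follow the table
  (calcification 0.333), which the tier-wise calcification frequencies
  support.
* **Unreported quantities**, fixed once as modeling choices: prior failed
  attempt 0.15 (plausible for a referral mix where half the patients have
  prior PCI); severe calcification given any calcification 0.5; severe
  angulation given a bend >= 45 degrees 1/3 (so the marginal is ~0.30,
  consistent with a mean PROGRESS score near 1.3); age normal (62.81,
  11.27) years truncated at 18; occlusion length truncated normal with sd
  17 mm and mean solved so P(>= 20 mm) = 0.882; Rentrop sub-grades on
  either side of the < 2 threshold split 50/50 (only the indicator enters
  any score).
* **Operators**: ten, in groups I-V with counts (2, 1, 2, 3, 2), each
  drawn uniformly inside its group's defining box (years [1,4] or [5,15];
  volume [20,59] or [60,120]; rate [0.70,0.89] or [0.90,0.99]). Cases are
  assigned to groups with procedure weights (5, 6, 13, 75, 45)/144 and
  uniformly to an operator within the group.
* **Outcomes**: technical success is Bernoulli in the case's difficulty
  tier with probabilities (0.990, 0.875, 0.538, 0.250); procedural success
  is technical success times an independent Bernoulli(128/131), so the
  endpoint nesting holds by construction.

Features are drawn **independently** at their marginals: the registry
reports no joint distribution, and inventing correlations would be less
defensible than stating independence. The consequence — visible in any
generated cohort — is a slightly milder score distribution than the real
registry (mean operator-CTO near 1.1 versus 1.78 reported, more cases in
the simple tier), because in real data adverse features co-occur. Passing
tests on generated cohorts therefore demonstrate that the estimators and
the pipeline are correct, not that the generator reproduces the registry's
joint feature structure. Fluoroscopy time, contrast dose and stent counts
are not simulated at all.

Randomness uses one root seed with fixed per-stage substreams (operators,
features, assignment, outcomes, agreement), so regenerating with an extra
downstream stage never changes earlier draws, and identical configurations
give byte-identical cohorts.

### The discrimination benchmark

`generate_auc_benchmark()` is a separate desk-scale generator for AUC
work: tier with probabilities (103, 24, 13, 4)/144, score within tier
uniform on {0, 1, 2} / point mass 3 / point mass 4 / uniform on {5, 6},
technical failure with tier probabilities 0.010/0.125/0.462/0.750. The
within-tier score distributions are a modeling choice (no within-tier
histogram is available); the closed-form expected AUC of the mixture,
computed by an independent pairwise-probability oracle in the test suite,
is 0.9025 — inside the 95 % interval (0.821-0.982) reported for the score
on real data, which is what makes it a useful benchmark. At n = 14,400 the
empirical Mann-Whitney AUC lands within a few thousandths of the
closed-form value.

## Evaluation methods and numerical choices

**Discrimination.** `auc_mann_whitney()` computes AUC by midranks (ties
count half), identical to the trapezoidal ROC area; the equivalence is a
tested invariant at 1e-12. Orientation: the positive class is *technical
failure* and higher scores predict it, which makes a good difficulty score
land above 0.5. `auc_ci()` uses the DeLong structural-components variance
with a normal interval truncated to [0, 1]; a seeded percentile bootstrap
(2,000 replicates) is available as an option. Both routes are cross-checked
against pROC in the test suite.

**Calibration.** An integer score is not a probability, so the
Hosmer-Lemeshow test is applied to a univariate logistic recalibration
P(failure) = logit^-1(a + b*score), fitted by glm's iteratively reweighted
least squares (Newton-Raphson for this likelihood) with convergence
tolerance 1e-10 and at most 100 iterations. Complete or quasi-complete
separation is detected (boundary fitted probabilities or a diverging slope)
and flagged, never silently returned. `hosmer_lemeshow()` groups cases by
ranked predicted probability into 10 near-equal groups by default — the
usual "deciles of risk"; the group count is a convention, not a fact about
any particular study. Tied probabilities stay in one group, so the realized
group count G can drop below 10; the statistic sum((O-E)^2 / (E(1-E/n)))
is referred to chi-square with G - 2 degrees of freedom, and when G < 3 the
result is reported with a degenerate-df flag and no p-value. A group whose
expected events are 0 or n makes the statistic undefined and is reported by
name as an error. Grouping by rank makes the statistic invariant under
strictly increasing transforms of the grouping variable. The test's type-I
error at nominal 5 % is verified by simulation in the acceptance suite.

**Agreement.** `cohen_kappa()` is unweighted kappa with marginal-product
expected agreement; the degenerate case of two identical constant raters
(expected agreement 1) is defined as kappa 1 with a flag.
`generate_rating_pairs()` provides the matching fixture: rater B copies
rater A with probability *a* else re-draws among the other k - 1
categories, giving asymptotic kappa (a - 1/k)/(1 - 1/k) — 0.80 at a = 0.85,
k = 4, the regime of a well-trained second reader.

**Display conventions.** Percentages are rounded half-up to one decimal in
exact integer arithmetic (`percent(131, 144)` is 91.0, immune to binary
floating point); AUC and kappa print to three decimals. Group-comparison
tests delegate to the standard implementations (Pearson chi-square without
continuity correction, Fisher's exact test, equal-variance one-way ANOVA,
tie-corrected Kruskal-Wallis) with explicit handling of the degenerate
inputs: zero within-group variance yields F = 0 for equal means and a
flagged infinite F otherwise; an all-tied sample yields H = 0.

**Degenerate cohorts.** A cohort in which every case has the same technical
outcome cannot support discrimination or calibration; `run_pipeline()`
returns a partial report with per-score skip reasons instead of failing,
and the CLI signals this with exit code 2. Missing values in a cohort CSV
are rejected with row numbers, never imputed: case records are adjudicated
data, and silence about a hole in them would be a bug factory.

## Problem sizes in the test suite

The acceptance-level checks run at the sizes that make their guarantees
meaningful while keeping the suite quick: exhaustive enumeration of all
4,096 score-variable combinations; 1,000 random instances for the
AUC-equivalence invariant; 200 simulations at n = 5,000 for the
Hosmer-Lemeshow size check; n = 50,000 for logistic parameter recovery
(+-0.05); n = 10,000 for generator marginal recovery within three binomial
standard errors; n = 14,400 for the discrimination benchmark. The whole
suite completes in well under a minute.

## Known limitations

* Independent feature margins understate the real co-occurrence of adverse
  features; tier occupancy of generated cohorts is skewed toward "simple"
  relative to a real registry. Joint-structure claims cannot be tested
  against this generator.
* The comparator scores are implemented exactly as the condensed point
  tables define them, not re-derived from their original publications;
  variables outside those tables (e.g. J-CTO's re-attempt timing rules)
  are out of scope. Published comparator evaluations differ on which
  comparators to include (one analysis lists CL for calibration but
  reports PROGRESS); `run_config(comparators = ...)` lets the user choose,
  defaulting to all five.
* The operator credit treats the three experience criteria as independent
  and additive. Real operator effects are unlikely to be additive in the
  tails (a 90 % first-year operator), which is why off-grid group
  combinations are flagged rather than silently classified.
* With four cases in an extremely-difficult tier of a 144-case cohort,
  per-tier percentages carry very wide uncertainty; the tier table reports
  counts alongside percentages for that reason, and empty tiers report NA
  percentages, not zero.
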