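---
title: "Methods: projecting the indirect costs of arthritis by static microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting the indirect costs of arthritis by static microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plycost)
```

## The problem and the model

Arthritis is one of the chronic conditions most likely to push older
workers (45--64 years) out of the labour force. Each person who is out
of the labour force because of their arthritis in a given year
represents a *lost productive life year* (lost PLY): the person loses
labour income, the government pays extra welfare and loses income-tax
revenue, and the economy loses output. `plycost` implements a static
microsimulation pipeline that quantifies those indirect costs for the
Australian 45--64 population over the projection years 2015, 2020, 2025
and 2030, in real 2013 Australian dollars throughout.

The pipeline has five stages:

1. **Base population.** Person-level records shaped like a pooled
   2003/2009 national disability survey: demographics, education,
   income-unit type, home ownership, labour-force status (including
   "not in the labour force due to own ill-health"), the main chronic
   condition as an ICD-10 category, hours band, pension-receipt flags,
   an income quintile and a survey weight. A person has lost a PLY to
   arthritis iff they are out of the labour force through their own
   ill-health *and* their main condition is in ICD-10 M00--M19
   ("arthritis and related disorders").
2. **Economic imputation.** Weekly income (earnings + other income +
   welfare), welfare payments and tax (income tax + Medicare levy) are
   attached to every person by exact-cell hot-deck matching against a
   donor pool shaped like a static tax-transfer model snapshot, on ten
   matching variables: labour force status, income unit type, income
   quintile, Age Pension receipt, DSP receipt, sex, age group, hours of
   work, education and home ownership.
3. **Projection.** Monetary amounts are uprated from the 2013 base year
   at 1% per annum real growth for incomes and taxes and 0% for welfare
   (welfare is price-indexed only); survey weights are recalibrated per
   projection year to external benchmark totals by GREG (GREGWT-style)
   calibration, with the 2003 and 2009 survey halves reweighted
   separately and pooled 50/50.
4. **Costing.** Weighted group summaries; covariate-adjusted median
   gaps between each labour-force-by-arthritis group and full-time
   workers without arthritis, from weighted median (quantile, tau = 0.5)
   regression on group indicators plus age, sex and education, with
   percentile bootstrap confidence intervals; national annual costs
   from per-person counterfactual gaps mixed over the probabilities of
   the lost-PLY person's labour-force destination absent arthritis.
5. **GDP impact.** Missing workers are converted to lost GDP by an
   average-product formula (GDP per full-time-equivalent worker-year,
   part-time workers counting a configurable FTE fraction, default
   0.5), and to the potential percentage gain in GDP.

The confidential microdata behind the original national estimates
(household survey unit records, tax-transfer model snapshots, dynamic
population projections) cannot be redistributed, so the package ships a
first-class synthetic-data generator that emulates their statistical
structure, and carries the published national projection table
(`plycost_reference()`) as the set of external inputs and calibration
anchors. Absolute national levels computed from the synthetic world are
therefore *emulations* calibrated to the published figures, not
re-estimates of them; the printed-arithmetic identities (growth
percentages, GDP ratios, population shares) are recomputed exactly from
the published inputs.

## The synthetic-data generator

`generator_config()` fixes the study conditions. Defaults:

* 25,104 survey records pooled over two survey years, weighted to a
  5,945,000-person population in 2015 (growing to 7,130,000 by 2030 via
  the benchmark paths).
* Labour-force-by-arthritis cell shares from the published 2015 column:
  48.98% full-time without arthritis, 5.16% full-time with arthritis,
  17.36% part-time without arthritis, 3.13% part-time with arthritis,
  0.91% out of the labour force due to arthritis. The residual is split
  between unemployment (1.99%), other-condition ill-health NILF (4.79%,
  matching the share of such respondents in the pooled survey) and
  other NILF.
* Per-group weekly income medians (2015 level) of 1308.88 / 1180.65 /
  602.86 / 551.77 / 321.87 AU$, a flat disability-pension rate of
  311.67 AU$/week, and a 2013-style progressive tax schedule
  (tax-free threshold 18,200 AU$/yr, marginal rates 19/32.5/37/45%,
  Medicare levy 1.5%).

Design choices worth recording:

* **Earnings are log-normal per group** with log-scale SDs of
  0.7--0.85 for workers; this is the simplest family reproducing the
  strong right skew of the published table (means far above medians).
  The log-location is calibrated by root-finding on the realized draws
  so that the *group median of total income at the 2015 reference year*
  lands on its target almost exactly; a closed-form log-normal location
  would miss for groups whose income mixes in flat welfare payments.
  Monetary targets are stated at 2015 level and deflated internally to
  the 2013 base year of the economic data.
* **Welfare is rule-based, not distributional**: flat payment rates by
  status (disability pension 311.67, unemployment allowance 255.25, a
  family-benefit top-up), because the published welfare medians are
  degenerate at the payment rates (311.67 for the lost-PLY group, 0 for
  workers). This is why the welfare median is reproduced exactly while
  income medians are reproduced to within sampling noise.
* **Covariate structure.** Earnings carry education and age-band
  multipliers, and the lost-PLY group is drawn older and less educated
  than full-time workers. Part of the raw median income gap
  (321.87 - 1308.88 = -987 AU$/wk) is therefore explained by age, sex
  and education, and the covariate-adjusted gap lands in the
  -700 AU$/wk region, consistent with the published adjusted estimate
  (-706.12); the generator is calibrated to that order, not to the
  exact figure. `balanced_covariates()` switches all of this off for
  simulation designs where groups must be exchangeable on covariates.
* **Group sizes are apportioned deterministically** (largest-remainder)
  rather than drawn multinomially, so configured shares are met within
  a fraction of a percentage point by construction; weights are mildly
  log-normal (SD 0.2 on the log scale) and normalised to the weighted
  population exactly.
* **The income quintile is derived from the record's own total income**
  against fixed weekly break points, so the quintile is consistent
  between survey records and donors by construction.

What the generator does *not* emulate: questionnaire structure, wealth,
within-household correlation, item nonresponse, severity of arthritis
(not collected in the source surveys), and any real-world correlation
not listed above. Passing tests on synthetic data therefore demonstrate
that the *pipeline machinery* is correct and well-calibrated, not that
the synthetic world reproduces every joint distribution of the
confidential data.

## Imputation

Matching is exact-cell hot-deck on the ten matching variables — the
standard reading of "synthetic matching" over categorical variables —
with ties broken by a seeded uniform draw rather than donor order, so
results are order-invariant and reproducible. When a recipient's cell
is empty, a fallback ladder drops variables one at a time: home
ownership, income unit type, Age Pension receipt, hours band,
education, then DSP receipt, income quintile, sex and age group. The
first five drops follow a least-outcome-predictive-first ordering; the
remaining four exist because with ~40,000 donors a rare cell (e.g. a
high-quintile ill-health NILF record) can genuinely lack a donor, and
a ladder that terminates at a labour-force-status-only match guarantees
termination without ever crossing the analysis's stratifier. Fallback
depth is recorded per recipient for audit, and imputation is a pure
function of (recipients, donors, policy, seed).

## Calibration reweighting

The production implementation of the survey-reweighting algorithm used
by the national statistics office is not published; the package
implements the documented family: chi-square-distance
(generalized-regression) calibration. New weights minimise
$\sum_i (w_i - d_i)^2 / d_i$ subject to $X'w = T$, giving
$w = d\,(1 + X\lambda)$ with $\lambda = (X'DX)^{+}(T - X'd)$; weights
breaching the multiplicative bounds (default $[0.1, 10]\times$ the
design weight) are clamped and the free records re-solved until no new
clamps appear (at most `max_iter` = 50 passes, relative tolerance
1e-6). The solver is verified against the closed-form solution on
small instances and against calibration identities, not against the
official software. The pseudoinverse handles the deliberate rank
deficiency of overlapping constraint sets (several full partitions of
the same population); the right-hand side is consistent, so any
solution of the normal equations calibrates exactly.

Benchmarks per projection year are age-by-sex totals, labour-force-by-
arthritis analysis-cell totals, and marginals for education, home
ownership and DSP receipt. The analysis cells are constrained jointly
(rather than labour-force totals and an arthritis-prevalence total
separately) because the reported per-year group counts are pinned only
by the joint cells; the arthritis prevalence trend is embedded in the
cell-share trajectories and can be perturbed via
`apply_disease_trend()`, which rescales arthritis cells and
redistributes the complement so the year total is conserved to machine
precision.

## Costing choices

* **Weighted median convention:** the *lower* weighted median — the
  smallest observed value whose cumulative weight reaches half the
  total. With rule-based welfare this reports the actual payment rate.
* **Adjusted gaps:** weighted quantile regression (tau = 0.5) of the
  outcome on group indicators plus age group, sex and education;
  confidence intervals by case-resampling percentile bootstrap
  (convention: 1000 replications), seeded. Percentile intervals of a
  median can be asymmetric and need not cover the point estimate; the
  package asserts only `ci_low <= ci_high`. In a groups-only design the
  coefficients collapse to differences of weighted group medians, which
  is the oracle the test suite checks against at 1e-8.
* **Counterfactual destinations:** the weighted FT/PT/unemployed
  distribution of labour-force participants without arthritis,
  standardised to the age-by-sex profile of the lost-PLY group, with
  the unemployment probability taken as the complement so the three
  probabilities sum to one exactly.
* **National aggregation** uses regression-predicted counterfactuals
  for each lost-PLY person (mirroring "adjusted for age, sex and
  education") rather than raw group medians; the unemployed destination
  contributes no earnings gap and a welfare level equal to the
  unemployment-allowance rule; weekly amounts are annualised at 52
  weeks. Destination probabilities are a fixed input to the bootstrap;
  the regression counterfactuals are refit in every resample.
* **Headcounts** are reported rounded to the nearest 1,000 (the printed
  convention); unrounded values are retained internally. Growth
  percentages round half away from zero, as do currency (2 dp) and GDP
  percentage gains.

The GDP attribution (average product per FTE with a 0.5 part-time
factor) is a documented package decision: the official projection
method is not public, so published absolute GDP losses are treated as
externally given inputs whose *ratios* the package recomputes. In the
pipeline, GDP per FTE is stated at the 2013 base year (default
136,100 AU$/worker-year, the value implied by the published 2015 loss
and missing-worker split) and grows at the uprating rule's real income
growth rate, so labour productivity moves with real earnings. The
missing-worker counts used for GDP (53/56/58/59 thousand) are carried
separately from the lost-PLY headcounts (54/58/59/61 thousand), because
the published table uses both series without reconciling them.

## Numerical and reproducibility notes

* One master seed per run; stage seeds (generator, donors, matching,
  per-year bootstrap streams) are derived deterministically from it, so
  any stage can be re-run in isolation. All derived seeds stay below
  2^31.
* The two generated survey years are calibrated separately to half of
  each year's benchmark totals (a 50/50 pooling convention, since the
  true survey-year composition is not published) and pooled.
* Degenerate inputs: empty groups summarise to `NA` with a warning
  rather than failing; an empty non-arthritis age-sex stratum makes the
  destination probabilities fall back to the unstandardised
  distribution with a warning; rank-deficient regression designs fail
  fast naming the collinear term; infeasible calibration targets
  (outside the weight-bound capacity) and non-convergence raise errors
  carrying the achieved gap.
* Problem sizes used by the test-suite simulations: the calibration and
  median-target checks run at the full 25,104-record survey size;
  parameter recovery runs 100 replicates at 5,000 records and 200
  bootstrap replications; bootstrap coverage runs 500 simulations of
  n = 200 with 1,000 replications. The acceptance script runs the full
  pipeline at 25,104 records with 200 bootstrap replications.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(
  years = c(2015L, 2030L),
  generator = generator_config(),
  reps = 200L, seed = 1L
)
res <- run_pipeline(cfg)
render_table(res, 3)   # national costs with bootstrap CIs
res$metrics            # headline growth figures
autoplot(res)
```

## Known limitations

* Absenteeism, presenteeism and informal-carer costs are out of scope,
  as are direct health-system costs and intervention scenarios; the
  costing is participation-based only.
* Severity of arthritis is not modelled (not collected in the source
  surveys).
* The synthetic world draws covariates independently within groups;
  real household surveys carry richer dependence. National levels from
  synthetic runs are calibrated emulations of the published estimates,
  with fidelity limited by the published margins used as anchors.
* The calibration solver is "GREGWT-style": verified by calibration
  identities and a closed-form oracle, not by agreement with the
  official implementation.
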