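---
title: "A Markov cohort cost-utility model for statin-initiation risk thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model for statin-initiation risk thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statincua)
```

## The decision problem

Primary-prevention guidelines initiate statin therapy when an individual's
predicted 10-year atherosclerotic cardiovascular disease (ASCVD) risk
exceeds a threshold. Risk models differ in their endpoint: *hard* outcome
models predict non-fatal myocardial infarction (MI), fatal ischemic heart
disease (IHD) and ischemic stroke (IS); *soft* outcome models additionally
include non-MI non-fatal IHD events, which account for the large majority
of IHD events in Chinese adults. `statincua` evaluates, from a societal
perspective, which risk threshold — and which of the two screening models —
buys quality-adjusted life years (QALYs) at an acceptable cost.

## Model structure

The engine is an annual-cycle Markov cohort model over nine health states
(`health_states()`): two disease-free states (off/on statin), three
non-fatal ASCVD states (acute MI, other IHD, IS), two statin adverse-event
states (new-onset diabetes; a transient recovered-myopathy episode) and two
absorbing death states (fatal ASCVD, fatal non-ASCVD). Transitions among
the non-fatal ASCVD states are bidirectional (comorbidity and recurrence);
death states absorb all outgoing mass.

Disease-free first-event probabilities are supplied as sex- and
age-band-specific (nine 5-year bands, 30--34 to 70--75) 10-year cumulative
probabilities, stratified into statin-eligible, non-eligible and overall
populations at each threshold, and converted to annual probabilities with
the constant-rate formula

$$r = 1 - \exp\left(\tfrac{\ln(1-p)}{10}\right).$$

Transitions *after* the first event use whole-population average rates: the
data underlying any one stratum are too sparse to estimate post-event
pathways, so a single `("all", "all", "overall")` row set acts as the
fallback for all strata.

Each non-fatal event has an *acute stage* — the hospitalization portion of
the entry cycle, `days/365` of the year — and a *chronic stage* thereafter.
Entry cycles accrue the admission cost, the human-capital indirect cost of
the stay, and the pro-rated chronic cost and utility; subsequent cycles
accrue chronic values only. No half-cycle correction is applied: the model
follows the expected-value cohort convention of the decision-analysis
software this class of models is usually built in, and a correction would
change all strategies almost identically, leaving increments (the
quantities of interest) essentially untouched.

### Lifetime horizon and age extrapolation

Sub-cohorts enter at the midpoint of their age band and are propagated
until age 100 (by which point virtually no probability mass is alive under
any realistic mortality input). Ages beyond the oldest observed band carry
the 70--75 band's transition probabilities forward; this understates the
age gradient of mortality late in life, but affects all strategies alike.

### Treatment mechanics

While on statin therapy the annual probabilities of non-fatal IHD events
are multiplied by 0.67, non-fatal IS by 0.69 and fatal ASCVD by 0.83
(meta-analytic relative risks; 95% CIs drive the sensitivity analyses).
Treatment ends three ways:

* **adverse diabetes** (annual probability 0.0030): permanent transition to
  a chronic-diabetes state (utility 0.84, chronic cost \$835.87/yr) that
  retains the untreated disease-free ASCVD hazards — the evidence base
  gives no diabetes-specific ASCVD modification, so none is imposed;
* **definite myopathy** (annual probability 0.0024): one hospitalization
  episode (utility 0.56 during the stay), then return to untreated
  disease-free with no chronic sequela, since no chronic myopathy cost or
  utility is published;
* **discontinuation for other reasons** (probability 0.1186): applied once
  in the first treated cycle, reflecting a trial-level overall rate; an
  annual mode is available via `treatment_effects(discontinue_mode =
  "annual")`.

The adverse-event probabilities are published as trial percentages without
an explicit time basis; they are applied *annually* here (with the
configuration switch above the natural place to change that). Over a
lifetime horizon this is deliberately conservative against statin therapy:
a material share of the treated cohort eventually accrues the diabetes
disutility, which can offset part — in extreme inputs all — of the
prevention gain.

### Eligibility

Screening happens once, at model entry: individuals with predicted risk at
or above the threshold (ties eligible — the package treats "risk higher
than threshold" inclusively and documents it) enter the eligible stratum;
there is no re-screening at later ages. Strategy-level outcomes are the
eligible-fraction-weighted mixture of the treated eligible stratum and the
untreated non-eligible stratum, per (sex, age band) cell, aggregated with
census weights. The no-treatment comparator uses overall-population rows —
except when compared against the highest threshold of a grid, where it
reuses that threshold's stratified rows so the two strategies share inputs
(the comparability rule).

## Economic values

All money is in 2019 US\$ (6.9 RMB/US\$). Statin-treated disease-free
years cost \$61.43 (drug) + \$52.17 (registration) + \$4.35 (one
risk-assessment visit per treated year, charged annually because the
published fee is per visit without a stated frequency). Indirect costs use
the human-capital approach: a hospitalization costs
`(salary/365) × days × 2 × (1 − unemployment)` (patient plus one
caregiver; calendar-day wage because all lost time is assumed productive),
and a fatal ASCVD event at age $a$ under retirement age 60 (configurable;
not stated in the source material, 60 is the common Chinese retirement
anchor) costs the discounted employment-adjusted salary stream from $a$ to
60. Premature-death productivity loss is charged for fatal ASCVD only:
charging it for background mortality as well would add a near-identical
term to both arms of every comparison while making the no-treatment cost
baseline dominated by deaths unrelated to the decision.

Utility weights: 1 disease-free, 0.999 on statin, 0.5 during the acute
stage of any ASCVD event, 0.87/0.90/0.84 for chronic IHD/IS/diabetes, 0.56
during a myopathy stay, 0 after death. The statin disutility applies in
disease-free states only; once a patient has a chronic condition the
condition's utility is used alone (applying 0.999 multiplicatively there is
a configuration away, but the published values do not compose it).

Costs and QALYs are discounted at 5%/yr (sensitivity range 0--8%), cycle 0
undiscounted.

## Frontier analysis

Strategies are compared by incremental cost-effectiveness ratios (ICERs)
along the efficiency frontier. `build_frontier()` removes strictly
dominated strategies (higher cost, no more QALYs), then repeatedly removes
any strategy whose adjacent ICER exceeds that of the next more effective
strategy (extended dominance) until the ladder increases strictly; ICERs
are recomputed after each removal, so reported frontier ICERs are relative
to the *previous frontier strategy*, not the previous printed row.
`select_optimal()` walks the ladder and returns the most effective frontier
strategy whose ICER is within the willingness-to-pay (WTP); the package
uses the 2019 Chinese GDP per capita (\$10,274/QALY) and three times it
(\$30,823/QALY) as anchors. Equal-QALY ties keep the cheaper strategy;
fully identical pairs keep the first listed with a warning.

A worked example on the bundled published table:

```{r frontier}
soft <- reference_strategy_table("soft")
build_frontier(soft)
select_optimal(build_frontier(soft), 10274)$threshold
```

`matched_proportion_comparison()` pairs soft- and hard-model strategies
treating approximately the same population share (nearest eligible
fraction within 1 percentage point) and classifies the soft strategy as
strongly dominant, dominated, or reports the pairwise ICER.

## Sensitivity analysis

`one_way_sensitivity()`/`tornado()` re-run a two-strategy comparison with
one parameter at each bound. `run_psa()` draws all parameters jointly:
relative risks log-normal (meanlog $= \ln(\text{base})$, sdlog
$= (\ln hi - \ln lo)/3.92$), proportions and utilities beta, costs and
durations gamma (both method-of-moments with mean = base, sd
$= (hi-lo)/3.92$; the same 3.92 convention is used for ±15% bounds to keep
one rule). Each PSA iteration gets its own seed derived from the master
seed, so results do not depend on execution order and extending `n`
preserves the earlier iterations. Per iteration the optimal strategy is
the one maximizing net monetary benefit (QALYs × WTP − cost) — equivalent
to the ICER-ladder choice on the frontier but well defined iteration by
iteration; `acceptability_curve()` converts wins into probabilities over a
WTP grid (default 0--40,000 in 500-unit steps, spanning both anchors).

## The synthetic cohort

The transition inputs of the original analysis come from an
access-restricted biobank, so the package ships a generator whose defaults
*are* the published study conditions: ages 30--75 under a stylized 2019
census age structure, two sexes, ten regions (five urban, five rural), and
10-year risk scores with cohort medians of exactly 9.8% (soft) and 5.2%
(hard).

Risk is log-linear in a latent score $z$ (age + sex + Gaussian frailty,
median-centred and standardized): $\text{risk} = m \cdot e^{sz}$. The
scale $m$ is the target median (exact by construction); the spread $s$ is
solved by root-finding so that the expected fraction with a first event
within 12 years — under competing Gompertz background mortality, and for
hard events also competing with soft-only events, since only first events
are classified — equals the published 16.9% (soft) and 11.4% (hard). Two
anchors, two parameters, no tuning. The risk scores are simultaneously the
generative truth: each individual's first-event hazard is the
constant-rate equivalent of their 10-year risk, which is what makes
parameter-recovery testing possible (`estimate_transition_table()` must
give back, within binomial error, exactly what `generate_cohort()` put
in). A hard first event is an acute MI, IS or fatal ASCVD with
probabilities 0.20/0.55/0.25 — a fixed split chosen once to reflect that
non-MI IHD dominates IHD events in this population; soft-only events are
other IHD.

Ten-year stratum probabilities are simple proportions with censoring
treated as event-free, defensible because loss to follow-up in the
emulated cohort is below 1%. Post-first-event rows cannot be estimated
from first events, so the generator emits whole-population average rates
scaled by a recurrence multiplier (default 1.5) with event-specific annual
case-fatality additions (MI 0.030, other IHD 0.010, IS 0.025) — labelled
synthetic stand-ins: they make event states suitably more lethal than
disease-free life but are not estimates of any published quantity.

What the generator does *not* emulate: individual risk-factor covariates
(blood pressure, smoking, waist circumference), secular trends in event
rates, age-varying hazards within the follow-up window, and regional risk
heterogeneity beyond what `recalibrate_risk()` (a log-cumulative-hazard
rescaling to observed regional risks) can impose afterwards. Passing
pipeline tests on synthetic data therefore demonstrates internal
consistency of the machinery — generation, estimation, simulation,
economics, frontier — not external validity of any particular threshold
recommendation, and the absolute costs and QALYs of the original analysis
are not reproducible without its restricted transition inputs.

## Numerical choices and problem sizes

* Probability arithmetic is double precision; transition-matrix row
  residuals within $10^{-12}$ of zero are clipped and renormalized, larger
  deficits raise an error naming the stratum.
* Cohort traces conserve mass to $10^{-9}$ per cycle and absorbing-state
  occupancy is non-decreasing; both are asserted property-style under
  randomized matrices.
* Lifetime ASCVD fractions track *first-event entry mass* (flows from
  never-ASCVD states into ASCVD states), not point-in-time occupancy,
  which would double-count recurrences and miss post-event deaths.
* The test suite uses cohorts of 30,000--50,000 individuals for
  calibration recovery, 300--1000 random instances for the frontier
  oracle, and a 200-iteration PSA over a four-threshold grid; these sizes
  were chosen so the full suite exercises every stochastic claim at
  meaningful power while remaining a routine desk run.

## Known limitations

* Post-event transition inputs are synthetic constructions (see above);
  with real stratified inputs the same table schema drops in unchanged.
* The eligible/non-eligible stratification is exact only at the
  thresholds for which tables were estimated; there is no interpolation.
* Statin efficacy is assumed constant over the lifetime, and eligibility
  is assessed once at entry — both choices mirror the modelling tradition
  this package implements, and both flatter treatment somewhat.
* The adverse-event time basis (annual versus per-trial) is the single
  most consequential undocumented input; users comparing against other
  implementations should check this switch first.
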