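---
title: "Quantifying residual bias in retrospective case-control studies with negative controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying residual bias in retrospective case-control studies with negative controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ccbias` is a bench for a methodological question: how much residual bias
does a retrospective-database case-control design carry relative to a
self-controlled case series (SCCS) run on the same data, and can that bias
be measured with negative-control exposures and absorbed by empirical
p-value calibration? Everything runs on synthetic claims data with known
ground truth, so every estimate the package produces can be compared
against the truth that generated it.

## The simulation model

`simulate_population()` generates a minimal OMOP-like database: one row per
person (sex, birth date, a latent log frailty), one continuous observation
period per person, dispensing-level drug exposures, and dated condition
occurrences with an inpatient/outpatient flag.

**Confounding mechanism.** Each person carries a time-invariant log frailty
$f \sim \mathcal{N}(0, \texttt{frailty\_sd}^2)$. Frailty enters twice:

* the initiation rate of *every* drug is
  $\texttt{initiation\_rate} \times e^{\texttt{confounding\_strength} \cdot f}$
  chains per person-year, and
* the outcome log rate contains $f$ additively.

Sicker people are thus both treated more and sicker — the classic
time-invariant confounder. Setting `confounding_strength = 0` switches
confounding off while keeping outcome heterogeneity.

**Exposure process.** Each initiation starts a chain of 30-day dispensings;
the number of refills is geometric (`refill_prob = 0.5`, mean one refill)
and refill gaps are uniform on 0–45 days, so roughly a third of refills
exceed the 30-day persistence gap and split a chain into separate treatment
episodes — era construction downstream is deliberately nontrivial.

**Biological risk model.** A drug with true log rate ratio $\theta_d$
multiplies the outcome rate by $e^{\theta_d}$ during the treatment episode
(dispensings chained with the 30-day gap) from the day after initiation
until `risk_extension_days = 30` days after the last supplied day — a
30-day pharmacological carry-over consistent with 30-day supplies. Under
this definition the 30-day-extension SCCS risk window is correctly
specified, while the 365-day-extension variant deliberately over-extends,
as the replicated designs do. Negative-control drugs (`nc_01` …, 35 by
default) have $\theta_d = 0$ everywhere, which is what makes them usable as
bias probes.

**Outcome process.** Events arrive from an inhomogeneous Poisson process,
simulated exactly by thinning, with

$$\log \lambda(t) = \log(\texttt{baseline\_rate}) + f
  + \texttt{age\_slope} \cdot (\text{age}(t) - \text{age}_{\text{ref}})
  + \texttt{seasonal\_amplitude} \cdot \sin(2\pi \cdot \text{yearfrac}(t))
  + \textstyle\sum_d \theta_d \, \mathbb{1}[\text{at risk for } d \text{ at } t].$$

Each event is recorded inpatient with probability `inpatient_prob`. A
person's first event triggers, with probability `treatment_prob = 0.9`, a
dispensing of a dedicated outcome-treatment drug — this feeds the
diagnosis-plus-treatment path of the simple case rule. Each
negative-control drug also emits an indication condition 0–30 days before
first initiation (supporting indication-nested designs), and five generic
comorbidity conditions occur at rate `comorbidity_rate` × $e^f$ per year,
giving the balance table realistic frailty-correlated characteristics.

**Default study conditions.** The defaults are fixed once and used by the
tests and the acceptance script: 5000 persons, calendar window 2010–2014,
ages 18–65 at enrollment, `frailty_sd = 1.0`,
`confounding_strength = 0.5`, `baseline_rate = 0.03` events/person-year at
the reference age, `initiation_rate = 0.10` chains/person-year,
`seasonal_amplitude = 0.2`, `age_slope = 0.02`/year, 35 negative controls.
The confounding size was chosen from the approximation that the
case-control log-OR bias is roughly
$\texttt{confounding\_strength} \times \texttt{frailty\_sd}^2 = 0.5$,
comfortably past log 1.25, so the contrast between designs is unambiguous
at desk scale. The parameter-recovery study uses 2000 persons per
replicate with a single drug at true IRR 2 and a higher
`initiation_rate = 0.4` and `baseline_rate = 0.05` purely for statistical
information per replicate.

**Reproducibility.** Every random column draws from an RNG substream whose
seed is derived from `rng_seed` and a fixed label, with draws consumed in
person-major order; enlarging the population therefore appends new persons
without reshuffling existing ones, and the whole experiment is a pure
function of its configuration.

**What the generator does not emulate.** No drug-class ontology, no
dose/duration heterogeneity, no disease natural history or
outcome-dependent enrollment end, no regional or plan-level structure, and
confounding is purely time-invariant (the mechanism SCCS is immune to by
construction). Passing tests therefore demonstrate the estimators and the
diagnostic machinery, and the *direction* of the design contrast under
time-invariant confounding; they do not certify either design's behavior
under time-varying confounding or real claims idiosyncrasies.

## The two designs

### Simple population case-control

Cases satisfy the record-level rule "outcome code on three or more distinct
dates, or at least one code plus any dispensing of the outcome-treatment
drug"; the index date is the first diagnosis date. Controls come from the
never-case population with at least 12 months of enrollment, index date
exactly 12 months after enrollment start, matched greedily in case
index-date order on sex, age (730-day caliper) and enrollment length
(90-day caliper), sampling up to 3 controls uniformly without replacement.
Exposure is any drug era intersecting `[index − 365, index − 1]`; the index
day itself is excluded so same-day treatment of the outcome never counts as
prior exposure.

Two window conventions deserve note. First, cases must have at least 365
days of observation before index — otherwise part of a case's lookback
window precedes enrollment and is unobservable, which mechanically deflates
case exposure. Second, even with fully observed windows the design retains
a *structural* asymmetry: a case's window can be intersected by treatment
episodes initiated before the window began, while a control's window starts
on the first enrollment day, where exposure history is left-truncated. With
episode-length exposure this inflates the null odds ratio on its own,
independent of confounding. The package implements the design as specified
rather than papering over this: it is precisely the kind of residual bias
the negative-control machinery exists to expose. The estimator-level
unit test of null unbiasedness therefore uses single-day dispensings, for
which the artifact is structurally absent.

### Nested case-control

Cohort entry is the first fill of the entry drug among persons carrying the
indication diagnosis; eligibility needs 365 days of observation before and
183 days after entry and age ≥ 18. Cases are first inpatient outcome
occurrences on or after entry (persons with earlier inpatient outcomes are
excluded as prevalent). Up to four controls per case are matched on sex,
age (365-day caliper) and time in cohort (365-day caliper) among eligible,
outcome-free, still-observed members, inheriting the case's index date.
Exposure uses a 30-day window, and the outcome model adds the comorbidity
indicators (any occurrence in the prior year) and the severity score. For
negative controls the nesting cohort is that drug's own indication cohort,
mirroring how a nested design would be transported to other exposures.

### Conditional logistic regression

Estimation is by the exact conditional likelihood for 1:m sets: each set
contributes the case's linear predictor minus the log-sum of exponentiated
linear predictors over members. Newton–Raphson with step-halving runs to a
gradient sup-norm below 1e-8 (at most 100 iterations); standard errors come
from the inverse observed information. Covariate columns with no
within-set variation anywhere are dropped; a monotone likelihood (all
informative sets discordant the same way) is detected by coefficient
divergence (|β| > 15) and reported as non-estimable instead of a huge
finite number, and such exposures are excluded from calibration fitting.
For 1:1 sets with binary exposure the maximizer coincides with the
discordant-pair ratio, which the tests pin to 1e-6.

### Self-controlled case series

Drug eras (30-day persistence gap) become risk windows
`[era_start + 1, era_end + extension]` with `extension` 365 or 30 days;
overlapping windows merge, and each era carries a 30-day pre-exposure
window clipped wherever it meets exposed time (exposed status wins) or the
observation start. The first 365 days of each person's observation are
excluded to establish exposure status at the start of follow-up; persons
whose only events fall there contribute nothing and are dropped — the SCCS
conditions on cases, so this is a likelihood statement, not a data
deletion. Remaining time is cut at every calendar-month boundary and
window edge. Because intervals are closed integer-day sets, every day and
hence every event belongs to exactly one interval; interval lengths sum
exactly to included time (tested as an invariant).

Conditional on a person's event total, interval counts are multinomial with
probabilities proportional to `length × exp(linear predictor)`; person
intercepts cancel, which is the design's immunity to time-invariant
confounding. The linear predictor holds the exposure indicator, a separate
pre-exposure coefficient (estimated and reported, but never part of the
headline IRR — it absorbs contraindication-driven rate dips just before
treatment), and, when adjustment is on, two additive splines: a cubic
B-spline on age-in-months with boundary knots at the 5th/95th and interior
knots at the 27.5th/50th/72.5th percentiles of included person-time, and a
cyclic cubic spline on month-of-year with five knots over the year, both
evaluated at calendar-month midpoints (age and season are treated as
constant within a month). Whether age and season deserve one combined
calendar-time spline or two additive ones is genuinely open; two additive
splines keep the two time scales interpretable and identified, and the
cyclic constraint makes December continuous with January. Aliased or
degenerate basis columns (too little age variation, fewer than three
distinct months) are reduced or dropped with a message. Newton–Raphson
settings mirror the conditional logistic fitter.

## Calibration diagnostics

Each estimable negative-control log estimate $\hat\theta_i$ with standard
error $\tau_i$ is modeled as
$\hat\theta_i \sim \mathcal{N}(\mu, \sigma^2 + \tau_i^2)$; $(\mu, \sigma)$
are fitted by L-BFGS-B with $\sigma \ge 0$ (a boundary fit $\sigma = 0$ is
legitimate and reported). The calibrated p-value of any estimate is its
two-sided tail probability under that empirical null; at
$(\mu, \sigma) = (0, 0)$ it reduces *exactly* to the nominal Wald p-value.
The significance boundary at level $\alpha$ is
$\mu \pm z_{1-\alpha/2}\sqrt{\sigma^2 + \tau^2}$ over a grid of standard
errors, emitted as a plot-ready table next to the nominal $\pm z \tau$
line. A plain Gaussian bias model is used throughout; a heavier-tailed
variant would be a reasonable extension but is not needed to reproduce the
qualitative contrast. Calibrated confidence intervals are out of scope —
only p-values are calibrated.

Type-I error evaluation is leave-one-out: each control is calibrated
against a model fitted on the other controls, so no control is tested
against a null that contains it.

Covariate balance follows the usual convention: proportions of exposed and
unexposed persons with any occurrence of a characteristic in the year up to
a month before the anchor (exposure start for exposed, the 12-months-after-
enrollment index for unexposed; the last month is excluded to avoid
outcome precursors), compared by standardized difference with the 0.1
flag. When both proportions are degenerate and unequal the pooled variance
vanishes; the value is then capped at $\pm\sqrt{2}$, the formula's value
just inside the degenerate corner, rather than returned as infinite.

## Numerical choices, in one place

* Dates are integer days (R `Date` epoch); month arithmetic uses the
  proleptic Gregorian calendar. All windows are closed day intervals, so
  boundary-day ties cannot arise by construction.
* "12 months" is always 365 days, "6 months" 183 days, "2 years" 730 days.
* A dispensing gap of exactly 30 days merges into one era; 31 splits.
* Both likelihood fitters: Newton–Raphson, gradient tolerance 1e-8, max
  100 iterations, step-halving on any likelihood decrease, separation
  flagged at |β| > 15, initialized at β = 0.
* Systematic-error MLE: L-BFGS-B from (mean, sd) of the inputs, σ bounded
  at 0, `factr = 10`, `pgtol = 1e-10`; at least 5 estimable controls
  required.
* Wald CIs use the literal 1.96; calibrated boundaries use
  `qnorm(0.975)` so the boundary round-trips through `calibrated_p` at
  1e-10.
* Greedy matching processes cases in ascending index-date order and
  samples eligible candidates uniformly without replacement; the matching
  algorithm itself is unspecified in the replicated designs, and greedy
  sampling is the simplest scheme that respects "without replacement". A
  warning (never silence) is raised when more than 5% of cases match short.

## Problem sizes used by the test suite

The suite was sized to make every Monte-Carlo check decisive at desk
scale: parameter recovery runs 200 replicates of 2000 persons (SCCS mean
log IRR within 0.05 of log 2; CI coverage in [0.90, 0.98]); the
bias-contrast experiment runs the full default conditions (5000 persons,
35 negative controls, both designs); null-configuration unbiasedness runs
100 replicates of 500 persons per design; calibration recovery runs 500
replicates of 35 controls. The acceptance script reruns the contrast
experiment and the exact likelihood oracles from scratch at whatever seed
it is given.

## Known limitations

* Confounding is exclusively time-invariant, the case SCCS handles by
  construction; time-varying confounding (e.g. frailty drifting before
  treatment) would hit both designs and is only partially probed by the
  pre-exposure window.
* The SCCS assumes events do not alter subsequent observation or exposure;
  the simulator honors this (no outcome-dependent censoring), so the
  package cannot detect violations of that assumption.
* The nested design's negative-control nesting uses synthetic one-drug
  indication cohorts; real indication overlap across drugs is richer.
* Exposure misclassification is modeled only through the era/extension
  geometry; there is no dispensing non-adherence model.
* Estimates are one drug at a time, as in the replicated studies; joint
  multi-drug models are out of scope.
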