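# ccbias

Residual-bias diagnostics for case-control versus self-controlled designs
in retrospective claims-database studies.

## The problem

Case-control studies run inside administrative claims databases compare
persons with an outcome (cases) against matched persons without it
(controls), and estimate an odds ratio (OR) for prior drug exposure by
conditional logistic regression. Because the design anchors on the outcome
date rather than the exposure date, exposed and unexposed members of such
studies can differ systematically — sicker patients are both treated more
and experience more outcomes — and the design offers few safe options to
adjust. The self-controlled case series (SCCS) asks the within-person
question instead — *given that a person had the outcome, was it more likely
during exposed time than unexposed time?* — and is therefore immune to
confounding by anything constant within a person.

`ccbias` makes this contrast measurable without access to any proprietary
database. It simulates longitudinal claims data (persons, enrollment spans,
dispensing chains, diagnoses) with a known confounding mechanism — a
per-person frailty that raises both treatment probability and outcome rate
— and a registry of true effects in which 35 *negative-control* drugs have
true rate ratio exactly 1. It then runs both study designs over every
negative control and quantifies how far each strays from the null.

It is aimed at methodologists and pharmacoepidemiologists who want a fully
reproducible bench for study-design diagnostics: covariate balance,
negative-control estimate distributions, and empirical p-value calibration.

## What is implemented

* **Synthetic claims simulator** (`simulation_config()`,
  `simulate_population()`): enrollment spans, per-drug Poisson initiation
  (log-rate shifted by `confounding_strength × log_frailty`), 30-day
  dispensings chained into treatment episodes with refill gaps, outcome
  events from an inhomogeneous Poisson process (frailty, age, season, and
  per-drug true log rate ratios), indication and comorbidity conditions,
  and a severity score correlated with frailty. Deterministic given one
  seed.
* **Cohort machinery** (`build_drug_eras()`, `identify_cases_crockett()`,
  `build_nesting_cohort_chou()`, `identify_cases_chou()`): drug eras with a
  30-day persistence gap; a simple population case rule (three diagnosis
  dates, or one diagnosis plus outcome treatment); a nested design with an
  indication-defined cohort, 12-month/6-month/age-18 eligibility and
  incident inpatient cases.
* **Case-control engine** (`match_controls_crockett()`,
  `match_controls_chou()`, `assess_exposure()`, `fit_conditional_logistic()`,
  `run_case_control_design()`): greedy caliper matching without replacement
  (age/sex/enrollment length, or age/sex/time-in-cohort with up to four
  controls), window-based exposure and covariate assessment, and
  conditional logistic regression maximized by Newton-Raphson on the exact
  conditional likelihood

  $$\ell(\beta) = \sum_s \Big( x_{\text{case}(s)}'\beta -
      \log \sum_{j \in s} e^{x_j'\beta} \Big).$$

* **SCCS engine** (`build_risk_windows()`, `partition_observation()`,
  `fit_sccs()`, `run_sccs_design()`): risk windows from the day after era
  start to 365 or 30 days past era end, 30-day pre-exposure windows,
  exclusion of the first 365 observation days, month-level intervals, and
  the conditional Poisson (per-person multinomial) likelihood

  $$\ell(\beta) = \sum_i \sum_k n_{ik} \log
      \frac{e_{ik} \, e^{x_{ik}'\beta}}{\sum_l e_{il}\, e^{x_{il}'\beta}},$$

  with five-knot cubic spline adjustment for age and a cyclic five-knot
  spline for season.
* **Calibration diagnostics** (`fit_systematic_error()`, `calibrated_p()`,
  `significance_boundary()`, `standardized_difference()`, `balance_table()`,
  `evaluate_error_rates()`): each negative-control log estimate
  $\hat\theta_i$ with standard error $\tau_i$ is modeled as
  $\mathcal{N}(\mu, \sigma^2 + \tau_i^2)$; $(\mu, \sigma)$ are fitted by
  maximum likelihood and p-values are recomputed against that empirical
  null. Balance tables report the standardized difference
  $(p_1 - p_2)\big/\sqrt{(p_1(1-p_1) + p_2(1-p_2))/2}$ with the usual 0.1
  flag.
* **Pipeline** (`run_experiment()`): simulate → both designs over all
  negative controls → calibration → balance → summary, exportable as CSV.

## Worked example

```r
library(ccbias)
cfg <- simulation_config(n_persons = 2000, n_negative_controls = 12,
                         baseline_rate = 0.05, initiation_rate = 0.2,
                         rng_seed = 7)
ex <- run_experiment(cfg)
ex$summary[, .(design, n_estimable, mean_abs_log_estimate,
               nominal_type1, calibrated_type1, bias_mu, bias_sigma)]
#>                   design n_estimable mean_abs_log_estimate nominal_type1
#> 1: case_control_crockett          12            0.78311235             1
#> 2:         sccs_crockett          12            0.09826431             0
#>    calibrated_type1    bias_mu bias_sigma
#> 1:        0.1666667 0.78257270 0.05841624
#> 2:        0.0000000 0.04858629 0.00000000
```

Every one of the 12 negative controls has a true OR of 1, yet the
case-control design calls *all twelve* significantly elevated
(`nominal_type1 = 1`) with a mean absolute log OR of 0.78 — pure residual
confounding, here injected by the frailty mechanism. The SCCS on the same
data is essentially unbiased (mean absolute log IRR 0.10, no false
positives). Empirical calibration absorbs the case-control bias into the
fitted error model (mu ≈ 0.78) and brings its type-I error back near the
nominal level. A single control illustrates the same story:

```r
ex$estimates[exposure == "nc_01",
             .(design, or_irr = round(exp(log_estimate), 2),
               p = signif(p_value, 2), cal_p = signif(calibrated_p_value, 2))]
#>                   design or_irr       p cal_p
#> 1: case_control_crockett   3.17 1.4e-09 0.063
#> 2:         sccs_crockett   1.18 2.9e-01 0.460
```

A truly null drug shows OR 3.17 (nominal p = 1.4e-9) under the case-control
design and IRR 1.18 (p = 0.29) under the SCCS. The balance table explains
why — exposed and unexposed persons differ well beyond the |S.Diff| > 0.1
convention:

```r
head(ex$balance[order(-abs(s_diff))], 3)
#>    characteristic p_exposed p_unexposed s_diff flagged
#> 1:       comorb_5     0.314       0.230   0.19    TRUE
#> 2:      ind_nc_04     0.123       0.187  -0.18    TRUE
#> 3:       comorb_2     0.290       0.221   0.16    TRUE
```

(At this small population size the matcher also warns that ~12% of cases
found fewer than three eligible controls; at the default 5000 persons the
warning disappears.)

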