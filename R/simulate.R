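#' Configuration for the synthetic claims simulator
#'
#' Defines the study conditions for a simulated longitudinal claims database:
#' a population of persons with one continuous enrollment span each, per-drug
#' dispensing chains that form treatment episodes, and an outcome whose rate
#' depends on a time-invariant person frailty, age, season, and current drug
#' exposure. The frailty raises both the outcome rate and (through
#' `confounding_strength`) the probability of starting any drug, which is the
#' confounding mechanism the diagnostics in this package are designed to
#' expose.
#'
#' @param n_persons number of persons.
#' @param start_date,end_date calendar window of the simulated data.
#' @param n_negative_controls number of negative-control drugs (true log rate
#'   ratio 0), named `nc_01`, `nc_02`, ...
#' @param min_age,max_age age range (years) at enrollment start.
#' @param frailty_sd standard deviation of the per-person log frailty.
#' @param confounding_strength multiplier linking log frailty to the log
#'   initiation rate of every drug; 0 switches confounding off.
#' @param baseline_rate outcome events per person-year at the reference age
#'   (midpoint of the age range), average season, frailty 0.
#' @param seasonal_amplitude amplitude of the sinusoidal log-rate modifier
#'   over the calendar year.
#' @param age_slope change in log outcome rate per year of age.
#' @param true_log_rr optional named numeric vector of additional drugs and
#'   their true log rate ratios during biologically exposed time (e.g.
#'   `c(drug_x = log(2))`). Negative-control drugs always carry 0; supplying
#'   a non-zero value for an `nc_*` identifier is an error.
#' @param initiation_rate per-drug initiation rate (chains per person-year at
#'   frailty 0); a scalar, or a named vector keyed by drug identifier.
#' @param days_supply days covered by one dispensing.
#' @param refill_prob geometric success probability for the number of refills
#'   after the initial fill (mean refills = (1-p)/p).
#' @param refill_gap_max refill gaps are uniform on 0..`refill_gap_max` days,
#'   so some chains exceed the 30-day persistence gap and split into
#'   separate treatment episodes.
#' @param persistence_gap_days gap that chains dispensings into one
#'   biological treatment episode.
#' @param risk_extension_days pharmacological carry-over: the elevated-rate
#'   period of an episode runs from the day after initiation through this
#'   many days after the last day of supply.
#' @param indication_window_days each negative-control drug's indication
#'   condition is recorded 0..this many days before first initiation.
#' @param treatment_prob probability that a person's first outcome event
#'   triggers a dispensing of the outcome-treatment drug (supports the
#'   diagnosis-plus-treatment path of the simple case rule).
#' @param inpatient_prob probability an outcome occurrence is recorded in the
#'   inpatient setting.
#' @param n_comorbidities,comorbidity_rate number and per-person-year rate of
#'   generic comorbidity conditions (`comorb_1`, ...) whose rate scales with
#'   frailty; used as balance-table characteristics and regression
#'   covariates.
#' @param severity_correlation target correlation between the synthetic
#'   severity score and log frailty (see [simulate_severity_score()]).
#' @param outcome_condition,treatment_drug concept identifiers.
#' @param rng_seed master seed; every random column draws from a substream
#'   derived from it, so enlarging the population does not reshuffle
#'   existing persons.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_persons = 5000L,
                              start_date = "2010-01-01",
                              end_date = "2014-12-31",
                              n_negative_controls = 35L,
                              min_age = 18, max_age = 65,
                              frailty_sd = 1.0,
                              confounding_strength = 0.5,
                              baseline_rate = 0.03,
                              seasonal_amplitude = 0.2,
                              age_slope = 0.02,
                              true_log_rr = NULL,
                              initiation_rate = 0.10,
                              days_supply = 30L,
                              refill_prob = 0.5,
                              refill_gap_max = 45L,
                              persistence_gap_days = 30L,
                              risk_extension_days = 30L,
                              indication_window_days = 30L,
                              treatment_prob = 0.9,
                              inpatient_prob = 0.8,
                              n_comorbidities = 5L,
                              comorbidity_rate = 0.3,
                              severity_correlation = 0.5,
                              outcome_condition = "outcome",
                              treatment_drug = "outcome_rx",
                              rng_seed = 1L) {
  stopifnot(
    n_persons > 0, frailty_sd >= 0, baseline_rate > 0,
    n_negative_controls >= 0, min_age < max_age,
    as_day(start_date) < as_day(end_date),
    refill_prob > 0, refill_prob <= 1,
    treatment_prob >= 0, treatment_prob <= 1,
    inpatient_prob >= 0, inpatient_prob <= 1,
    abs(severity_correlation) <= 1
  )
  negative_controls <- if (n_negative_controls > 0) {
    sprintf("nc_%02d", seq_len(n_negative_controls))
  } else character(0)
  truth <- setNames(rep(0, length(negative_controls)), negative_controls)
  if (!is.null(true_log_rr)) {
    stopifnot(!is.null(names(true_log_rr)), all(nzchar(names(true_log_rr))))
    bad <- intersect(names(true_log_rr), negative_controls)
    if (any(true_log_rr[bad] != 0)) {
      stop("negative-control drugs must have true log rate ratio 0")
    }
    truth[names(true_log_rr)] <- true_log_rr
  }
  drugs <- names(truth)                      # drugs with an initiation process
  truth[treatment_drug] <- 0                 # outcome treatment is causally null
  init <- if (length(initiation_rate) == 1L && is.null(names(initiation_rate))) {
    setNames(rep(initiation_rate, length(drugs)), drugs)
  } else {
    r <- setNames(rep(0.10, length(drugs)), drugs)
    stopifnot(all(names(initiation_rate) %in% drugs))
    r[names(initiation_rate)] <- initiation_rate
    r
  }
  structure(list(
    n_persons = as.integer(n_persons),
    start_date = start_date, end_date = end_date,
    n_negative_controls = as.integer(n_negative_controls),
    min_age = min_age, max_age = max_age,
    frailty_sd = frailty_sd,
    confounding_strength = confounding_strength,
    baseline_rate = baseline_rate,
    seasonal_amplitude = seasonal_amplitude,
    age_slope = age_slope,
    true_log_rr = truth,
    negative_controls = negative_controls,
    drugs = drugs,
    initiation_rate = init,
    days_supply = as.integer(days_supply),
    refill_prob = refill_prob,
    refill_gap_max = as.integer(refill_gap_max),
    persistence_gap_days = as.integer(persistence_gap_days),
    risk_extension_days = as.integer(risk_extension_days),
    indication_window_days = as.integer(indication_window_days),
    treatment_prob = treatment_prob,
    inpatient_prob = inpatient_prob,
    n_comorbidities = as.integer(n_comorbidities),
    comorbidity_rate = comorbidity_rate,
    severity_correlation = severity_correlation,
    outcome_condition = outcome_condition,
    treatment_drug = treatment_drug,
    rng_seed = as.integer(rng_seed)
  ), class = "simulation_config")
}

#' Simulate a longitudinal claims dataset with known ground truth
#'
#' Generates the four linked tables of a minimal OMOP-like claims database
#' (persons, observation periods, drug exposures, condition occurrences)
#' under the model described in [simulation_config()]. Outcome events follow
#' an inhomogeneous Poisson process, simulated exactly by thinning, with log
#' rate
#' `log(baseline_rate) + log_frailty + age_slope * (age - age_ref) +
#'  seasonal term + true_log_rr[d]` during any biologically at-risk time for
#' drug `d` (treatment episode plus carry-over). Deterministic given
#' `config$rng_seed`.
#'
#' @param config a [simulation_config()].
#' @return an object of class `claims_dataset`: a list with data.tables
#'   `persons` (person_id, sex, birth_date, log_frailty),
#'   `observation_periods` (person_id, obs_start, obs_end),
#'   `drug_exposures` (person_id, drug_id, start, end),
#'   `condition_occurrences` (person_id, condition_id, day, setting),
#'   plus `truth` (named vector of true log rate ratios covering every
#'   simulated drug), `negative_controls`, and the `config`. All dates are
#'   integer days since 1970-01-01.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_persons
  seed <- config$rng_seed
  w0 <- as_day(config$start_date)
  w1 <- as_day(config$end_date)
  min_days <- 731L
  stopifnot(w1 - w0 + 1L >= min_days)

  sex_draw <- with_substream(seed, "persons/sex", rbinom(n, 1, 0.5))
  sex <- ifelse(sex_draw == 1L, "F", "M")
  start_slack <- max(0L, min(365L, w1 - w0 + 1L - min_days))
  obs_start <- w0 + with_substream(seed, "persons/obs_start",
    as.integer(floor(runif(n, 0, start_slack + 1))))
  max_extra <- pmax(0L, w1 - (obs_start + min_days - 1L))
  obs_end <- obs_start + min_days - 1L +
    with_substream(seed, "persons/obs_len",
      as.integer(floor(runif(n) * (max_extra + 1))))
  age0 <- with_substream(seed, "persons/age",
    runif(n, config$min_age, config$max_age))
  birth <- as.integer(round(obs_start - age0 * 365.25))
  frailty <- with_substream(seed, "persons/frailty",
    rnorm(n, 0, config$frailty_sd))

  persons <- data.table(person_id = seq_len(n), sex = sex,
                        birth_date = birth, log_frailty = frailty)
  obs <- data.table(person_id = seq_len(n),
                    obs_start = obs_start, obs_end = obs_end)
  span <- obs_end - obs_start + 1L
  t_years <- span / 365.25

  ## ---- drug dispensing chains -------------------------------------------
  exposures <- vector("list", length(config$drugs))
  names(exposures) <- config$drugs
  for (d in config$drugs) {
    lam <- config$initiation_rate[[d]] *
      exp(config$confounding_strength * frailty)
    cnt <- with_substream(seed, c("init_count", d), rpois(n, lam * t_years))
    N <- sum(cnt)
    if (N == 0L) next
    pid <- rep(seq_len(n), cnt)
    u_t <- with_substream(seed, c("init_time", d), runif(N))
    init <- obs_start[pid] + as.integer(floor(u_t * span[pid]))
    nref <- with_substream(seed, c("refills", d), rgeom(N, config$refill_prob))
    fid <- rep(seq_len(N), nref + 1L)
    j <- sequence(nref + 1L) - 1L
    total <- length(fid)
    u_g <- with_substream(seed, c("gaps", d), runif(total))
    g <- ifelse(j == 0L, 0L,
                as.integer(floor(u_g * (config$refill_gap_max + 1L))))
    dtf <- data.table(chain = fid, g = g)
    dtf[, cg := cumsum(g), by = chain]
    fstart <- init[fid] + j * config$days_supply + dtf$cg
    fend <- fstart + config$days_supply - 1L
    pid_f <- pid[fid]
    keep <- fstart <= obs_end[pid_f]
    if (!any(keep)) next
    exposures[[d]] <- data.table(
      person_id = pid_f[keep], drug_id = d,
      start = as.integer(fstart[keep]),
      end = as.integer(pmin(fend[keep], obs_end[pid_f[keep]]))
    )
  }
  drug_exposures <- rbindlist(exposures)
  if (!nrow(drug_exposures)) {
    drug_exposures <- data.table(person_id = integer(), drug_id = character(),
                                 start = integer(), end = integer())
  }

  ## ---- outcome events by thinning ---------------------------------------
  r0 <- config$baseline_rate / 365.25
  age_ref <- (config$min_age + config$max_age) / 2
  amp <- config$seasonal_amplitude
  effect_drugs <- config$drugs[config$true_log_rr[config$drugs] != 0]
  pos_extra <- sum(pmax(config$true_log_rr[effect_drugs], 0))
  age_term_hi <- pmax(config$age_slope * (age_years(obs_start, birth) - age_ref),
                      config$age_slope * (age_years(obs_end, birth) - age_ref))
  log_lam_max <- log(r0) + frailty + age_term_hi + abs(amp) + pos_extra
  m_cand <- with_substream(seed, "outcome/count",
    rpois(n, exp(log_lam_max) * span))
  M <- sum(m_cand)
  cond_rows <- list()
  events <- data.table(person_id = integer(), day = integer())
  if (M > 0L) {
    pid_c <- rep(seq_len(n), m_cand)
    u_t <- with_substream(seed, "outcome/times", runif(M))
    cday <- obs_start[pid_c] + as.integer(floor(u_t * span[pid_c]))
    cand <- data.table(cid = seq_len(M), person_id = pid_c, day = cday)
    extra <- numeric(M)
    for (d in effect_drugs) {
      de <- drug_exposures[drug_id == d]
      if (!nrow(de)) next
      win <- biological_risk_windows(de, config)
      if (!nrow(win)) next
      hit <- cand[win, on = .(person_id, day >= start, day <= end),
                  which = TRUE, nomatch = 0L]
      extra[unique(hit)] <- extra[unique(hit)] + config$true_log_rr[[d]]
    }
    log_lam <- log(r0) + frailty[pid_c] +
      config$age_slope * (age_years(cday, birth[pid_c]) - age_ref) +
      amp * sin(2 * pi * year_fraction(cday)) + extra
    u_a <- with_substream(seed, "outcome/accept", runif(M))
    acc <- u_a < exp(log_lam - log_lam_max[pid_c])
    if (any(acc)) {
      ev_pid <- pid_c[acc]
      ev_day <- cday[acc]
      u_s <- with_substream(seed, "outcome/setting", runif(sum(acc)))
      cond_rows$outcome <- data.table(
        person_id = ev_pid, condition_id = config$outcome_condition,
        day = ev_day,
        setting = ifelse(u_s < config$inpatient_prob, "inpatient", "outpatient")
      )
      events <- data.table(person_id = ev_pid, day = ev_day)
    }
  }

  ## ---- outcome-treatment dispensing at first event ----------------------
  if (nrow(events)) {
    fe <- events[, .(first_event = min(day)), by = person_id][order(person_id)]
    u_r <- with_substream(seed, "treatment", runif(nrow(fe)))
    treat <- fe[u_r < config$treatment_prob]
    if (nrow(treat)) {
      tr <- data.table(
        person_id = treat$person_id, drug_id = config$treatment_drug,
        start = treat$first_event,
        end = pmin(treat$first_event + config$days_supply - 1L,
                   obs_end[treat$person_id])
      )
      drug_exposures <- rbind(drug_exposures, tr)
    }
  }

  ## ---- indication conditions for negative controls ----------------------
  for (d in config$negative_controls) {
    de <- drug_exposures[drug_id == d]
    if (!nrow(de)) next
    fi <- de[, .(first_init = min(start)), by = person_id][order(person_id)]
    u_i <- with_substream(seed, c("indication", d), runif(nrow(fi)))
    off <- as.integer(floor(u_i * (config$indication_window_days + 1L)))
    cond_rows[[paste0("ind_", d)]] <- data.table(
      person_id = fi$person_id,
      condition_id = paste0("ind_", d),
      day = pmax(fi$first_init - off, obs_start[fi$person_id]),
      setting = "outpatient"
    )
  }

  ## ---- generic comorbidity conditions -----------------------------------
  for (k in seq_len(config$n_comorbidities)) {
    lam <- config$comorbidity_rate * exp(frailty) * t_years
    cnt <- with_substream(seed, c("comorb_count", k), rpois(n, lam))
    K <- sum(cnt)
    if (K == 0L) next
    pid_k <- rep(seq_len(n), cnt)
    u_k <- with_substream(seed, c("comorb_time", k), runif(K))
    cond_rows[[paste0("comorb_", k)]] <- data.table(
      person_id = pid_k,
      condition_id = paste0("comorb_", k),
      day = obs_start[pid_k] + as.integer(floor(u_k * span[pid_k])),
      setting = "outpatient"
    )
  }

  condition_occurrences <- rbindlist(cond_rows)
  if (!nrow(condition_occurrences)) {
    condition_occurrences <- data.table(person_id = integer(),
                                        condition_id = character(),
                                        day = integer(), setting = character())
  }
  setorder(drug_exposures, person_id, drug_id, start, end)
  setorder(condition_occurrences, person_id, condition_id, day)

  structure(list(
    persons = persons,
    observation_periods = obs,
    drug_exposures = drug_exposures,
    condition_occurrences = condition_occurrences,
    truth = config$true_log_rr,
    negative_controls = config$negative_controls,
    config = config
  ), class = "claims_dataset")
}

# Biologically at-risk time of a drug: treatment episodes (dispensings
# chained with the persistence gap) from the day after initiation through
# risk_extension_days after the last supplied day, overlaps merged.
biological_risk_windows <- function(exposures, config) {
  eras <- build_drug_eras(exposures,
                          persistence_gap = config$persistence_gap_days)
  if (!nrow(eras)) return(data.table(person_id = integer(),
                                     start = integer(), end = integer()))
  merge_intervals(eras[, .(person_id,
                           start = era_start + 1L,
                           end = era_end + config$risk_extension_days)])
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat("<claims_dataset>\n")
  cat(sprintf("  persons:               %d\n", nrow(x$persons)))
  cat(sprintf("  observation periods:   %d\n", nrow(x$observation_periods)))
  cat(sprintf("  drug exposure records: %d (%d drugs)\n",
              nrow(x$drug_exposures),
              length(unique(x$drug_exposures$drug_id))))
  cat(sprintf("  condition occurrences: %d (%d concepts)\n",
              nrow(x$condition_occurrences),
              length(unique(x$condition_occurrences$condition_id))))
  cat(sprintf("  negative controls:     %d\n", length(x$negative_controls)))
  invisible(x)
}

#' Check referential integrity and date containment of a claims dataset
#'
#' Asserts unique person ids, one observation period per person, all drug
#' exposure and condition records referring to known persons with dates
#' inside that person's observation period, birth preceding every record,
#' and the truth registry covering every simulated drug.
#'
#' @param dataset a `claims_dataset`.
#' @return invisibly TRUE; stops with a message on the first violation.
#' @export
validate_claims_dataset <- function(dataset) {
  p <- dataset$persons
  o <- dataset$observation_periods
  stopifnot(
    !anyDuplicated(p$person_id),
    !anyDuplicated(o$person_id),
    all(o$person_id %in% p$person_id),
    all(o$obs_start <= o$obs_end)
  )
  lk <- merge(o, p[, .(person_id, birth_date)], by = "person_id")
  stopifnot(all(lk$birth_date <= lk$obs_start))
  de <- merge(dataset$drug_exposures, o, by = "person_id")
  stopifnot(
    all(de$start <= de$end),
    all(de$start >= de$obs_start), all(de$end <= de$obs_end)
  )
  co <- merge(dataset$condition_occurrences, o, by = "person_id")
  stopifnot(
    all(co$day >= co$obs_start), all(co$day <= co$obs_end),
    all(co$setting %in% c("inpatient", "outpatient"))
  )
  stopifnot(all(unique(dataset$drug_exposures$drug_id) %in%
                  names(dataset$truth)))
  invisible(TRUE)
}

#' Synthetic disease-severity score
#'
#' An integer score in 0..13 per person, marginally Binomial(13, 0.35),
#' whose Gaussian latent variable correlates with the person's log frailty
#' at a configurable level. It stands in for a published complications
#' severity index (whose code lists are not modeled here) as an adjustment
#' covariate that partially captures the confounder.
#'
#' @param dataset a `claims_dataset`.
#' @param correlation target correlation with log frailty; defaults to the
#'   config's `severity_correlation`.
#' @param seed defaults to the config's `rng_seed`.
#' @return data.table (person_id, severity_score).
#' @export
simulate_severity_score <- function(dataset, correlation = NULL, seed = NULL) {
  cfg <- dataset$config
  if (is.null(correlation)) correlation <- cfg$severity_correlation
  if (is.null(seed)) seed <- cfg$rng_seed
  f <- dataset$persons$log_frailty
  n <- length(f)
  z <- with_substream(seed, "severity", rnorm(n))
  latent <- if (n > 1 && sd(f) > 0) {
    correlation * as.vector(scale(f)) + sqrt(1 - correlation^2) * z
  } else {
    z
  }
  data.table(person_id = dataset$persons$person_id,
             severity_score = as.integer(qbinom(pnorm(latent), 13L, 0.35)))
}
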