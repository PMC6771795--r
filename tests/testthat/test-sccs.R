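test_that("risk windows follow the era + extension rule with pre-exposure", {
  era <- data.table(person_id = 1L, drug_id = "a",
                    era_start = 100L, era_end = 160L)
  w <- build_risk_windows(era, extension_days = 30L)
  expect_equal(w$risk, data.table(person_id = 1L, start = 101L, end = 190L))
  expect_equal(w$pre, data.table(person_id = 1L, start = 70L, end = 99L))

  ## eras whose extended windows overlap merge into one risk window, and
  ## the second era's pre-exposure window disappears inside exposed time
  eras2 <- data.table(person_id = 1L, drug_id = "a",
                      era_start = c(100L, 220L), era_end = c(160L, 260L))
  w2 <- build_risk_windows(eras2, extension_days = 365L)
  expect_equal(w2$risk, data.table(person_id = 1L, start = 101L, end = 625L))
  expect_equal(w2$pre, data.table(person_id = 1L, start = 70L, end = 99L))

  ## pre-exposure clipped at observation start
  obs <- data.table(person_id = 1L, obs_start = 90L, obs_end = 1000L)
  w3 <- build_risk_windows(era, extension_days = 30L,
                           observation_periods = obs)
  expect_equal(w3$pre, data.table(person_id = 1L, start = 90L, end = 99L))

  ## pre-exposure window truncated where it overlaps a prior risk window
  eras4 <- data.table(person_id = 1L, drug_id = "a",
                      era_start = c(100L, 210L), era_end = c(160L, 290L))
  w4 <- build_risk_windows(eras4, extension_days = 30L)
  expect_equal(w4$risk, data.table(person_id = 1L, start = c(101L, 211L),
                                   end = c(190L, 320L)))
  # second era's raw pre window [180, 209] loses [180, 190] to exposed time
  expect_equal(w4$pre, data.table(person_id = 1L, start = c(70L, 191L),
                                  end = c(99L, 209L)))
})

test_that("partition conserves time, excludes the first year, cuts at months", {
  obs <- data.table(person_id = 1L, obs_start = d("2010-01-15"),
                    obs_end = d("2012-03-20"))
  birth <- data.table(person_id = 1L, birth_date = d("1970-01-01"))
  ev <- data.table(person_id = 1L, day = d("2011-06-10"))
  nowin <- list(risk = data.table(person_id = integer(), start = integer(),
                                  end = integer()),
                pre = data.table(person_id = integer(), start = integer(),
                                 end = integer()))
  iv <- partition_observation(obs, ev, nowin, birth)
  included <- obs$obs_end - (obs$obs_start + 365L) + 1L
  expect_equal(sum(iv$days), included)
  expect_true(all(!iv$exposed) && all(!iv$pre_exposure))
  expect_equal(sum(iv$events), 1L)
  ## intervals never span a calendar month boundary
  expect_true(all(format(as.Date(iv$start, origin = "1970-01-01"), "%Y-%m") ==
                    format(as.Date(iv$end, origin = "1970-01-01"), "%Y-%m")))
  ## an event inside the excluded first year drops the person entirely
  ev_early <- data.table(person_id = 1L, day = obs$obs_start + 200L)
  expect_equal(nrow(partition_observation(obs, ev_early, nowin, birth)), 0L)
})

test_that("partition splits at window edges and assigns events uniquely", {
  obs <- data.table(person_id = 1L, obs_start = 0L, obs_end = 1500L)
  birth <- data.table(person_id = 1L, birth_date = -10000L)
  era <- data.table(person_id = 1L, drug_id = "a",
                    era_start = 700L, era_end = 760L)
  win <- build_risk_windows(era, extension_days = 30L,
                            observation_periods = obs)
  ev <- data.table(person_id = 1L, day = c(705L, 705L, 1200L, 680L))
  iv <- partition_observation(obs, ev, win, birth)
  expect_equal(sum(iv$days), 1500L - 365L + 1L)
  expect_equal(sum(iv$events), 4L)
  expect_equal(iv[exposed == TRUE, sum(days)], 790L - 701L + 1L)
  expect_equal(iv[exposed == TRUE, sum(events)], 2L)
  expect_equal(iv[pre_exposure == TRUE, sum(days)], 30L)
  expect_equal(iv[pre_exposure == TRUE, sum(events)], 1L)
  expect_true(all(iv$days >= 1L))
  ## no day belongs to two intervals
  expect_equal(sum(iv$days), uniqueN(unlist(Map(seq.int, iv$start, iv$end))))
})

test_that("single-person two-state closed form is recovered to 1e-8", {
  iv <- data.table(person_id = 1L, start = c(1L, 101L), end = c(100L, 500L),
                   days = c(100L, 400L), events = c(2L, 2L),
                   exposed = c(TRUE, FALSE), pre_exposure = FALSE,
                   month_of_year = c(1L, 2L), age_months = c(480, 490))
  fit <- fit_sccs(iv, adjust_age_season = FALSE)
  expect_lt(abs(exp(fit$log_estimate) - 4.0), 1e-8)
  ## equal rates in both states: IRR exactly 1
  iv1 <- copy(iv)[, events := c(1L, 4L)]
  fit1 <- fit_sccs(iv1, adjust_age_season = FALSE)
  expect_lt(abs(exp(fit1$log_estimate) - 1.0), 1e-8)
})

test_that("conditioning removes person-level rate multipliers", {
  set.seed(31)
  iv <- rbindlist(lapply(1:15, function(p) {
    data.table(person_id = p, start = c(1L, 101L, 201L),
               end = c(100L, 200L, 400L),
               days = c(100L, 100L, 200L),
               events = rpois(3, c(2, 1, 2)),
               exposed = c(TRUE, FALSE, FALSE), pre_exposure = FALSE,
               month_of_year = c(1L, 2L, 3L), age_months = 400 + p)
  }))
  iv <- iv[, if (sum(events) > 0) .SD, by = person_id]
  fit <- fit_sccs(iv, adjust_age_season = FALSE)
  ## scaling one person's interval lengths by a constant shifts that
  ## person's offset uniformly; the conditional likelihood is unchanged
  iv2 <- copy(iv)[person_id == 1L, days := days * 7L]
  fit2 <- fit_sccs(iv2, adjust_age_season = FALSE)
  expect_equal(fit$log_estimate, fit2$log_estimate, tolerance = 1e-8)
})

test_that("unadjusted SCCS matches Poisson regression with person effects", {
  set.seed(77)
  iv <- rbindlist(lapply(1:25, function(p) {
    n_iv <- sample(2:4, 1)
    len <- sample(50:300, n_iv)
    expo <- c(TRUE, rep(FALSE, n_iv - 1))
    lam <- len / 100 * ifelse(expo, 2.5, 1) * exp(rnorm(1, 0, 0.5))
    data.table(person_id = p, start = 1L, end = 1L, days = len,
               events = rpois(n_iv, lam), exposed = expo,
               pre_exposure = FALSE, month_of_year = 1L, age_months = 500)
  }))
  iv <- iv[, if (sum(events) > 0 && any(exposed) && any(!exposed)) .SD,
           by = person_id]
  fit <- fit_sccs(iv, adjust_age_season = FALSE)
  gl <- stats::glm(events ~ exposed + factor(person_id) + offset(log(days)),
                   family = stats::poisson(), data = iv)
  expect_equal(fit$log_estimate, unname(coef(gl)["exposedTRUE"]),
               tolerance = 1e-6)
  expect_equal(fit$standard_error,
               unname(sqrt(diag(vcov(gl)))["exposedTRUE"]),
               tolerance = 1e-4)
})

test_that("unadjusted design estimate is invariant to shifting all dates", {
  cfg <- simulation_config(n_persons = 500, n_negative_controls = 1,
                           baseline_rate = 0.2, initiation_rate = 0.3,
                           rng_seed = 15)
  ds <- simulate_population(cfg)
  eras <- build_drug_eras(ds$drug_exposures[drug_id == "nc_01"])
  ev <- ds$condition_occurrences[condition_id == "outcome", .(person_id, day)]
  birth <- ds$persons[, .(person_id, birth_date)]
  run <- function(shift) {
    obs <- copy(ds$observation_periods)[, `:=`(obs_start = obs_start + shift,
                                               obs_end = obs_end + shift)]
    er <- copy(eras)[, `:=`(era_start = era_start + shift,
                            era_end = era_end + shift)]
    win <- build_risk_windows(er, extension_days = 30L,
                              observation_periods = obs)
    iv <- partition_observation(obs, copy(ev)[, day := day + shift], win,
                                birth)
    fit_sccs(iv, adjust_age_season = FALSE)
  }
  f0 <- run(0L)
  f1 <- run(137L)
  expect_equal(f0$log_estimate, f1$log_estimate, tolerance = 1e-8)
  expect_equal(f0$standard_error, f1$standard_error, tolerance = 1e-8)
})

test_that("run_sccs_design is deterministic and labels its output", {
  cfg <- simulation_config(n_persons = 600, n_negative_controls = 1,
                           baseline_rate = 0.15, initiation_rate = 0.3,
                           rng_seed = 23)
  ds <- simulate_population(cfg)
  e1 <- run_sccs_design(ds, "chou", "nc_01")
  e2 <- run_sccs_design(ds, "chou", "nc_01")
  expect_identical(e1$log_estimate, e2$log_estimate)
  expect_equal(e1$design, "sccs_chou")
  expect_equal(e1$exposure, "nc_01")
  expect_true(e1$estimable)
})
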