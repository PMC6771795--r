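library(survival)

test_that("population matching enforces sex, age and enrollment calipers", {
  ## case person 1 + three candidates differing in one matching variable
  persons <- data.table(
    person_id = 1:5, sex = c("F", "F", "F", "F", "M"),
    birth_date = c(d("1970-01-01"), d("1971-07-01"),  # 1.5y gap: eligible
                   d("1972-07-01"),                   # 2.5y gap: too far
                   d("1970-01-01"), d("1970-01-01")),
    log_frailty = 0)
  obs <- data.table(
    person_id = 1:5,
    obs_start = d("2010-01-01"),
    obs_end = c(d("2013-12-31"), d("2014-01-30"),     # 30d length gap: ok
                d("2013-12-31"), d("2013-06-30"),     # 184d gap: too far
                d("2013-12-31")))                     # wrong sex
  ds <- make_test_dataset(persons, obs)
  cases <- data.table(person_id = 1L, index_date = d("2011-01-01"))
  expect_warning(
    sets <- match_controls_crockett(cases, ds, ratio = 3L, seed = 1),
    "fewer than")
  expect_equal(sets[is_case == FALSE, sort(person_id)], 2L)
  ## control index date is 12 months after enrollment start
  expect_equal(sets[is_case == FALSE, index_date],
               d("2010-01-01") + 365L)
})

test_that("abundant candidates give full sets without replacement", {
  base <- uniform_persons(200)
  cases <- data.table(person_id = 1:20, index_date = d("2011-06-15"))
  ds <- make_test_dataset(base$persons, base$observation_periods)
  sets <- match_controls_crockett(cases, ds, ratio = 3L, seed = 4)
  per_set <- sets[, .(n_ctrl = sum(!is_case)), by = set_id]
  expect_true(all(per_set$n_ctrl == 3L))
  ctrls <- sets[is_case == FALSE, person_id]
  expect_false(anyDuplicated(ctrls) > 0)        # without replacement
  expect_true(length(intersect(ctrls, cases$person_id)) == 0)
})

test_that("matching is seed-reproducible and seed-sensitive", {
  base <- uniform_persons(120)
  cases <- data.table(person_id = 1:10, index_date = d("2011-06-15"))
  ds <- make_test_dataset(base$persons, base$observation_periods)
  s1 <- match_controls_crockett(cases, ds, seed = 11)
  s2 <- match_controls_crockett(cases, ds, seed = 11)
  s3 <- match_controls_crockett(cases, ds, seed = 12)
  expect_identical(s1, s2)
  expect_false(identical(s1[is_case == FALSE, person_id],
                         s3[is_case == FALSE, person_id]))
  expect_identical(s1[is_case == TRUE], s3[is_case == TRUE])
})

test_that("exposure window is [index - w, index - 1]", {
  idx <- d("2012-06-01")
  members <- data.table(set_id = 1L, person_id = 1L, is_case = TRUE,
                        index_date = idx)
  era <- function(s, e) data.table(person_id = 1L, drug_id = "x",
                                   era_start = s, era_end = e)
  # era ending 10 days before index, window 30 -> exposed
  expect_true(assess_exposure(members, era(idx - 60L, idx - 10L), 30L)$exposed)
  # era ending 40 days before index, window 30 -> unexposed
  expect_false(assess_exposure(members, era(idx - 80L, idx - 40L), 30L)$exposed)
  # era starting on the index day -> unexposed (index day excluded)
  expect_false(assess_exposure(members, era(idx, idx + 30L), 30L)$exposed)
  # era ending exactly the day before index -> exposed
  expect_true(assess_exposure(members, era(idx - 40L, idx - 1L), 30L)$exposed)
})

test_that("covariate lookback covers the year before index", {
  base <- uniform_persons(2)
  co <- data.table(person_id = c(1L, 1L), condition_id = "comorb_1",
                   day = c(d("2012-06-01") - 100L, d("2012-06-01") - 400L),
                   setting = "outpatient")
  ds <- make_test_dataset(base$persons, base$observation_periods,
                          condition_occurrences = co)
  members <- data.table(set_id = 1L, person_id = 1:2,
                        is_case = c(TRUE, FALSE),
                        index_date = d("2012-06-01"))
  sev <- data.table(person_id = 1:2, severity_score = c(3L, 0L))
  mm <- assess_covariates_chou(members, ds, sev,
                               condition_concepts = c("comorb_1", "comorb_2"))
  expect_equal(mm$comorb_1, c(TRUE, FALSE))     # day -100 in, -400 out
  expect_equal(mm$comorb_2, c(FALSE, FALSE))    # member with no records
  expect_equal(mm$severity_score, c(3L, 0L))
})

test_that("conditional logistic MLE matches the discordant-pair closed form", {
  mk_pairs <- function(n_case_exp, n_ctrl_exp, n_concordant = 5) {
    n <- n_case_exp + n_ctrl_exp + n_concordant
    rbindlist(lapply(seq_len(n), function(i) {
      expo <- if (i <= n_case_exp) c(TRUE, FALSE)
      else if (i <= n_case_exp + n_ctrl_exp) c(FALSE, TRUE)
      else c(TRUE, TRUE)
      data.table(set_id = i, is_case = c(TRUE, FALSE), exposed = expo)
    }))
  }
  fit <- fit_conditional_logistic(mk_pairs(10, 5))
  expect_lt(abs(exp(fit$log_estimate) - 2.0), 1e-6)
  ## balanced discordance: OR exactly 1 by symmetry
  fit1 <- fit_conditional_logistic(mk_pairs(7, 7))
  expect_lt(abs(exp(fit1$log_estimate) - 1.0), 1e-8)
})

test_that("optimizer beats a dense grid and matches survival::clogit", {
  set.seed(99)
  members <- rbindlist(lapply(1:50, function(i) {
    data.table(set_id = i, is_case = c(TRUE, rep(FALSE, 3)),
               exposed = runif(4) < 0.4)
  }))
  fit <- fit_conditional_logistic(members)
  ll_fit <- attr(fit, "loglik")
  grid <- seq(-5, 5, length.out = 500)
  ll_grid <- vapply(grid, function(b) brute_clogit_loglik(members, b),
                    numeric(1))
  expect_gte(ll_fit, max(ll_grid))
  ## internal loglik agrees with the independent brute-force one
  expect_equal(conditional_logistic_loglik(members, fit$log_estimate),
               brute_clogit_loglik(members, fit$log_estimate),
               tolerance = 1e-10)
  ## cross-check coefficient and SE against survival::clogit
  sv <- survival::clogit(is_case ~ exposed + strata(set_id), data = members)
  expect_equal(fit$log_estimate, unname(coef(sv)), tolerance = 1e-6)
  expect_equal(fit$standard_error, unname(sqrt(diag(vcov(sv)))),
               tolerance = 1e-6)
})

test_that("multivariable conditional logistic matches survival::clogit", {
  set.seed(123)
  members <- rbindlist(lapply(1:60, function(i) {
    data.table(set_id = i, is_case = c(TRUE, rep(FALSE, 3)),
               exposed = runif(4) < 0.4,
               cov_a = runif(4) < 0.3,
               cov_b = rpois(4, 2))
  }))
  fit <- fit_conditional_logistic(members,
                                  terms = c("exposed", "cov_a", "cov_b"))
  sv <- survival::clogit(
    is_case ~ exposed + cov_a + cov_b + strata(set_id), data = members)
  expect_equal(attr(fit, "coefficients")$estimate, unname(coef(sv)),
               tolerance = 1e-6)
})

test_that("the likelihood is invariant to set order", {
  set.seed(7)
  members <- rbindlist(lapply(1:30, function(i) {
    data.table(set_id = i, is_case = c(TRUE, rep(FALSE, 2)),
               exposed = runif(3) < 0.5)
  }))
  fit1 <- fit_conditional_logistic(members)
  perm <- members[sample(.N)]
  fit2 <- fit_conditional_logistic(perm)
  expect_equal(fit1$log_estimate, fit2$log_estimate, tolerance = 1e-10)
})

test_that("one-directional discordance is reported as non-estimable", {
  members <- rbindlist(lapply(1:12, function(i) {
    data.table(set_id = i, is_case = c(TRUE, FALSE),
               exposed = c(TRUE, FALSE))
  }))
  fit <- fit_conditional_logistic(members)
  expect_false(fit$estimable)
  expect_true(is.na(fit$log_estimate))
  expect_match(fit$note, "separation|monotone")
})

test_that("nested matching uses case index dates and the at-risk rule", {
  base <- uniform_persons(40)
  de <- data.table(person_id = 1:40, drug_id = "oad",
                   start = d("2011-06-01"), end = d("2011-06-30"))
  co <- rbind(
    data.table(person_id = 1:40, condition_id = "t2dm",
               day = d("2011-05-01"), setting = "outpatient"),
    data.table(person_id = 1L, condition_id = "outcome",
               day = d("2013-02-01"), setting = "inpatient"))
  obs <- copy(base$observation_periods)
  obs[person_id == 2L, obs_end := d("2012-12-31")]  # gone before index
  ds <- make_test_dataset(base$persons, obs, de, co)
  nest <- build_nesting_cohort_chou(ds, "t2dm", "oad")
  cases <- identify_cases_chou(ds, nest)
  sets <- match_controls_chou(cases, nest, ds, seed = 2)
  expect_equal(sets[, sum(is_case)], 1L)
  expect_equal(sets[, sum(!is_case)], 4L)          # up to four controls
  expect_true(all(sets$index_date == d("2013-02-01")))
  expect_false(2L %in% sets$person_id)             # not at risk at index
})
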