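library(data.table)

# integer day from ISO string
d <- function(s) as.integer(as.Date(s))

# Assemble a claims_dataset from hand-built tables (fixtures are always
# constructed in code, never stored).
make_test_dataset <- function(persons, observation_periods,
                              drug_exposures = NULL,
                              condition_occurrences = NULL,
                              truth = NULL, config = NULL) {
  if (is.null(drug_exposures)) {
    drug_exposures <- data.table(person_id = integer(), drug_id = character(),
                                 start = integer(), end = integer())
  }
  if (is.null(condition_occurrences)) {
    condition_occurrences <- data.table(person_id = integer(),
                                        condition_id = character(),
                                        day = integer(), setting = character())
  }
  if (is.null(config)) {
    config <- simulation_config(n_persons = max(1L, nrow(persons)),
                                n_negative_controls = 0L)
  }
  if (is.null(truth)) {
    truth <- setNames(rep(0, length(unique(drug_exposures$drug_id))),
                      unique(drug_exposures$drug_id))
  }
  structure(list(
    persons = as.data.table(persons),
    observation_periods = as.data.table(observation_periods),
    drug_exposures = as.data.table(drug_exposures),
    condition_occurrences = as.data.table(condition_occurrences),
    truth = truth,
    negative_controls = character(0),
    config = config
  ), class = "claims_dataset")
}

# n persons with identical demographics and a shared enrollment span:
# convenient when matching candidates must be abundant.
uniform_persons <- function(n, sex = "F", birth = d("1970-06-15"),
                            obs_start = d("2010-01-01"),
                            obs_end = d("2014-12-31")) {
  list(
    persons = data.table(person_id = seq_len(n), sex = sex,
                         birth_date = birth, log_frailty = 0),
    observation_periods = data.table(person_id = seq_len(n),
                                     obs_start = obs_start, obs_end = obs_end)
  )
}

# Independent brute-force conditional-logistic log-likelihood used as an
# oracle against the package's Newton-Raphson fitter.
brute_clogit_loglik <- function(members, beta) {
  sum(vapply(split(members, members$set_id), function(s) {
    eta <- beta * as.numeric(s$exposed)
    eta[s$is_case] - log(sum(exp(eta)))
  }, numeric(1)))
}
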