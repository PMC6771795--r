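# Greedy risk-set matching with calipers. Both matchers process cases in
# ascending index-date order, sample eligible candidates uniformly without
# replacement (a control is used in at most one set and is never itself a
# case), and drop sets with zero matched controls. When more than 5% of
# cases obtain fewer controls than requested, a warning is raised rather
# than silently passing.

#' Match population controls to cases (simple design)
#'
#' Controls come from the overall population (persons never satisfying the
#' case rule) with at least 12 months of enrollment; a control's index date
#' is exactly 12 months after enrollment start. Cases must likewise have at
#' least `control_index_offset` days of enrollment before their index date,
#' so that the exposure window is fully observed for cases and controls
#' alike (otherwise early-enrollment cases mechanically look less exposed).
#' Eligibility requires equal sex, age at index within `age_caliper_days`,
#' and total enrollment length within `enrollment_caliper_days`.
#'
#' @param cases data.table (person_id, index_date) from
#'   [identify_cases_crockett()].
#' @param dataset a `claims_dataset`.
#' @param ratio controls per case (default 3).
#' @param age_caliper_days age caliper (default 730 days = 2 years).
#' @param enrollment_caliper_days enrollment-length caliper (default 90).
#' @param seed sampling seed.
#' @param control_index_offset days after enrollment start defining the
#'   control index date (default 365).
#' @return data.table of set members: set_id, person_id, is_case, index_date.
#' @export
match_controls_crockett <- function(cases, dataset, ratio = 3L,
                                    age_caliper_days = 730L,
                                    enrollment_caliper_days = 90L,
                                    seed = 1L,
                                    control_index_offset = 365L) {
  p <- merge(dataset$persons, dataset$observation_periods, by = "person_id")
  pool <- p[!(person_id %in% cases$person_id)]
  pool[, enroll_days := obs_end - obs_start + 1L]
  pool[, ctrl_index := obs_start + as.integer(control_index_offset)]
  pool <- pool[obs_end >= ctrl_index]            # >= 12 months of enrollment
  pool[, age_days := ctrl_index - birth_date]

  cs <- merge(cases, p, by = "person_id")
  cs <- cs[index_date - obs_start >= control_index_offset]
  cs[, enroll_days := obs_end - obs_start + 1L]
  cs[, age_days := index_date - birth_date]
  setorder(cs, index_date, person_id)

  n_pool <- nrow(pool)
  avail <- rep(TRUE, n_pool)
  pool_sex <- pool$sex
  pool_age <- pool$age_days
  pool_enr <- pool$enroll_days

  set.seed(seed)
  out <- vector("list", nrow(cs))
  short <- 0L
  for (i in seq_len(nrow(cs))) {
    elig <- which(avail &
                    pool_sex == cs$sex[i] &
                    abs(pool_age - cs$age_days[i]) <= age_caliper_days &
                    abs(pool_enr - cs$enroll_days[i]) <= enrollment_caliper_days)
    take <- if (length(elig) > ratio) {
      elig[sample.int(length(elig), ratio)]
    } else elig
    if (length(take) < ratio) short <- short + 1L
    if (!length(take)) next
    avail[take] <- FALSE
    out[[i]] <- data.table(
      set_id = i,
      person_id = c(cs$person_id[i], pool$person_id[take]),
      is_case = c(TRUE, rep(FALSE, length(take))),
      index_date = c(cs$index_date[i], pool$ctrl_index[take])
    )
  }
  if (nrow(cs) > 0 && short / nrow(cs) > 0.05) {
    warning(sprintf(
      "%d of %d cases (%.1f%%) matched fewer than %d controls",
      short, nrow(cs), 100 * short / nrow(cs), ratio))
  }
  sets <- rbindlist(out)
  if (!nrow(sets)) {
    sets <- data.table(set_id = integer(), person_id = integer(),
                       is_case = logical(), index_date = integer())
  }
  sets[]
}

#' Match cohort controls to cases (nested design)
#'
#' Controls come from eligible nesting-cohort members who are free of an
#' inpatient outcome through the case's index date and still under
#' observation on that date; they inherit the case's index date. Eligibility
#' requires equal sex, age within `age_caliper_days`, and time in cohort
#' within `time_in_cohort_caliper_days`. Up to `max_ratio` controls per case.
#'
#' @param cases data.table from [identify_cases_chou()].
#' @param nesting output of [build_nesting_cohort_chou()].
#' @param dataset a `claims_dataset`.
#' @param max_ratio maximum controls per case (default 4).
#' @param age_caliper_days default 365 (1 year).
#' @param time_in_cohort_caliper_days default 365 (1 year).
#' @param seed sampling seed.
#' @param condition outcome condition used for the outcome-free requirement.
#' @return data.table of set members: set_id, person_id, is_case, index_date.
#' @export
match_controls_chou <- function(cases, nesting, dataset, max_ratio = 4L,
                                age_caliper_days = 365L,
                                time_in_cohort_caliper_days = 365L,
                                seed = 1L,
                                condition = dataset$config$outcome_condition) {
  el <- nesting[eligible == TRUE & !(person_id %in% cases$person_id)]
  pool <- merge(el, dataset$persons[, .(person_id, sex, birth_date)],
                by = "person_id")
  pool <- merge(pool, dataset$observation_periods, by = "person_id")
  first_ip <- dataset$condition_occurrences[
    condition_id == condition & setting == "inpatient",
    .(first_event = min(day)), by = person_id]
  pool <- merge(pool, first_ip, by = "person_id", all.x = TRUE)

  cs <- merge(cases, dataset$persons[, .(person_id, sex, birth_date)],
              by = "person_id")
  setorder(cs, index_date, person_id)

  avail <- rep(TRUE, nrow(pool))
  set.seed(seed)
  out <- vector("list", nrow(cs))
  short <- 0L
  for (i in seq_len(nrow(cs))) {
    idx <- cs$index_date[i]
    elig <- which(avail &
                    pool$sex == cs$sex[i] &
                    pool$obs_start <= idx & pool$obs_end >= idx &
                    pool$cohort_entry_date <= idx &
                    (is.na(pool$first_event) | pool$first_event > idx) &
                    abs((idx - pool$birth_date) -
                          (idx - cs$birth_date[i])) <= age_caliper_days &
                    abs(pool$cohort_entry_date -
                          cs$nesting_entry_date[i]) <= time_in_cohort_caliper_days)
    take <- if (length(elig) > max_ratio) {
      elig[sample.int(length(elig), max_ratio)]
    } else elig
    if (length(take) < max_ratio) short <- short + 1L
    if (!length(take)) next
    avail[take] <- FALSE
    out[[i]] <- data.table(
      set_id = i,
      person_id = c(cs$person_id[i], pool$person_id[take]),
      is_case = c(TRUE, rep(FALSE, length(take))),
      index_date = idx
    )
  }
  if (nrow(cs) > 0 && short / nrow(cs) > 0.05) {
    warning(sprintf(
      "%d of %d cases (%.1f%%) matched fewer than %d controls",
      short, nrow(cs), 100 * short / nrow(cs), max_ratio))
  }
  sets <- rbindlist(out)
  if (!nrow(sets)) {
    sets <- data.table(set_id = integer(), person_id = integer(),
                       is_case = logical(), index_date = integer())
  }
  sets[]
}
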