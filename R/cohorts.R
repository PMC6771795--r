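#' Chain dispensing records into drug eras
#'
#' Per person and drug, records sorted by start date are merged into
#' treatment eras whenever the next record starts no more than
#' `persistence_gap` days after the running era end (a gap of exactly the
#' persistence gap still merges; one day more splits). Overlapping input
#' records are legal and merged; the era end is the maximum end among merged
#' records. The operation is idempotent.
#'
#' @param exposures data.table/data.frame with person_id, drug_id, start, end
#'   (integer days or Dates).
#' @param persistence_gap maximum allowed days between the end of one
#'   dispensing and the start of the next within one era (default 30).
#' @return data.table (person_id, drug_id, era_start, era_end) sorted by
#'   person, drug, era_start; eras of one person-drug pair are separated by
#'   more than `persistence_gap` days.
#' @export
build_drug_eras <- function(exposures, persistence_gap = 30L) {
  x <- as.data.table(exposures)
  if (!nrow(x)) {
    return(data.table(person_id = integer(), drug_id = character(),
                      era_start = integer(), era_end = integer()))
  }
  x <- x[, .(person_id, drug_id, start = as_day(start), end = as_day(end))]
  stopifnot(all(x$start <= x$end))
  x <- x[order(person_id, drug_id, start, end)]
  x[, prev_end := shift(cummax(end)), by = .(person_id, drug_id)]
  x[, new_era := is.na(prev_end) | start > prev_end + as.integer(persistence_gap)]
  x[, era := cumsum(new_era), by = .(person_id, drug_id)]
  out <- x[, .(era_start = min(start), era_end = max(end)),
           by = .(person_id, drug_id, era)]
  out[, era := NULL]
  setorder(out, person_id, drug_id, era_start)
  out[]
}

#' Identify cases under the simple population case rule
#'
#' A person is a case when the record contains health-care contacts with the
#' outcome code on at least three different dates, or at least one outcome
#' code together with any exposure to a drug used to treat the outcome. The
#' index date is the first outcome diagnosis date; a person is counted at
#' most once.
#'
#' @param dataset a `claims_dataset`.
#' @param condition outcome condition identifier (default: the simulated
#'   outcome).
#' @param treatment_drugs character vector of drug identifiers regarded as
#'   treatments for the outcome (default: the simulated treatment drug).
#' @return data.table (person_id, index_date), possibly empty.
#' @export
identify_cases_crockett <- function(dataset,
                                    condition = dataset$config$outcome_condition,
                                    treatment_drugs = dataset$config$treatment_drug) {
  occ <- dataset$condition_occurrences[condition_id == condition]
  if (!nrow(occ)) return(data.table(person_id = integer(), index_date = integer()))
  agg <- occ[, .(n_dates = uniqueN(day), first_day = min(day)), by = person_id]
  treated <- unique(dataset$drug_exposures[drug_id %in% treatment_drugs, person_id])
  cases <- agg[n_dates >= 3L | person_id %in% treated]
  setorder(cases, person_id)
  cases[, .(person_id, index_date = first_day)]
}

#' Build a nesting cohort of diagnosed-and-treated persons
#'
#' Cohort membership requires at least one diagnosis of the indication
#' condition (any setting, anywhere in the record) and at least one fill of
#' an entry drug; the cohort entry date is the first such fill. Eligibility
#' additionally requires continuous observation for at least `prior_days`
#' before and `post_days` after entry, and age at least `min_age_years` at
#' entry.
#'
#' @param dataset a `claims_dataset`.
#' @param indication_condition condition identifier defining the nesting
#'   indication (e.g. `"ind_nc_01"` for a negative control's indication).
#' @param entry_drugs drug identifiers whose first fill defines cohort entry.
#' @param prior_days,post_days required observation around entry (defaults:
#'   365 and 183 days, i.e. 12 and 6 months).
#' @param min_age_years minimum age at entry (default 18).
#' @return data.table (person_id, cohort_entry_date, eligible).
#' @export
build_nesting_cohort_chou <- function(dataset, indication_condition,
                                      entry_drugs,
                                      prior_days = 365L, post_days = 183L,
                                      min_age_years = 18) {
  dx <- unique(dataset$condition_occurrences[
    condition_id == indication_condition, person_id])
  fills <- dataset$drug_exposures[drug_id %in% entry_drugs & person_id %in% dx]
  if (!nrow(fills)) {
    return(data.table(person_id = integer(), cohort_entry_date = integer(),
                      eligible = logical()))
  }
  ent <- fills[, .(cohort_entry_date = min(start)), by = person_id]
  ent <- merge(ent, dataset$observation_periods, by = "person_id")
  ent <- merge(ent, dataset$persons[, .(person_id, birth_date)],
               by = "person_id")
  ent[, eligible :=
        cohort_entry_date - obs_start >= prior_days &
        obs_end - cohort_entry_date >= post_days &
        age_years(cohort_entry_date, birth_date) >= min_age_years]
  setorder(ent, person_id)
  ent[, .(person_id, cohort_entry_date, eligible)]
}

#' Identify cases within a nesting cohort
#'
#' Among eligible cohort members, a case is the first inpatient occurrence
#' of the outcome condition on or after cohort entry; persons with an
#' inpatient outcome before entry are excluded (incident cases only). The
#' index date is the diagnosis date.
#'
#' @param dataset a `claims_dataset`.
#' @param nesting output of [build_nesting_cohort_chou()].
#' @param condition outcome condition identifier.
#' @return data.table (person_id, index_date, nesting_entry_date).
#' @export
identify_cases_chou <- function(dataset, nesting,
                                condition = dataset$config$outcome_condition) {
  el <- nesting[eligible == TRUE]
  occ <- dataset$condition_occurrences[
    condition_id == condition & setting == "inpatient" &
      person_id %in% el$person_id]
  if (!nrow(occ)) {
    return(data.table(person_id = integer(), index_date = integer(),
                      nesting_entry_date = integer()))
  }
  occ <- merge(occ, el[, .(person_id, cohort_entry_date)], by = "person_id")
  prior <- unique(occ[day < cohort_entry_date, person_id])
  cases <- occ[day >= cohort_entry_date & !(person_id %in% prior),
               .(index_date = min(day),
                 nesting_entry_date = cohort_entry_date[1L]),
               by = person_id]
  setorder(cases, person_id)
  cases[]
}
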