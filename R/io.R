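#' Write a claims dataset to CSV files with a schema manifest
#'
#' Writes persons.csv, observation_periods.csv, drug_exposures.csv,
#' condition_occurrences.csv and truth.csv (RFC 4180, ISO-8601 dates,
#' UTF-8) plus manifest.json documenting column names and types.
#'
#' @param dataset a `claims_dataset`.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_claims_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  to_iso <- function(dt, cols) {
    out <- copy(as.data.table(dt))
    for (cc in cols) out[, (cc) := as.character(day_to_date(get(cc)))]
    out
  }
  tables <- list(
    persons = to_iso(dataset$persons, "birth_date"),
    observation_periods = to_iso(dataset$observation_periods,
                                 c("obs_start", "obs_end")),
    drug_exposures = to_iso(dataset$drug_exposures, c("start", "end")),
    condition_occurrences = to_iso(dataset$condition_occurrences, "day"),
    truth = data.table(drug_id = names(dataset$truth),
                       true_log_rr = unname(dataset$truth))
  )
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  manifest <- lapply(tables, function(tb) {
    lapply(tb, function(col) {
      if (is.character(col) && all(grepl("^\\d{4}-\\d{2}-\\d{2}$",
                                         col[!is.na(col)]))) "date"
      else if (is.integer(col)) "integer"
      else if (is.numeric(col)) "number"
      else if (is.logical(col)) "boolean"
      else "string"
    })
  })
  jsonlite::write_json(
    list(format = "ccbias-claims-v1",
         date_format = "ISO-8601 (YYYY-MM-DD)",
         negative_controls = dataset$negative_controls,
         tables = manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a claims dataset written by [write_claims_dataset()]
#'
#' @param dir directory containing the CSV tables and manifest.
#' @return a `claims_dataset` (without the originating `config`).
#' @export
read_claims_dataset <- function(dir) {
  rd <- function(nm) as.data.table(utils::read.csv(
    file.path(dir, paste0(nm, ".csv")), stringsAsFactors = FALSE))
  from_iso <- function(dt, cols) {
    for (cc in cols) dt[, (cc) := as_day(as.Date(get(cc)))]
    dt
  }
  persons <- from_iso(rd("persons"), "birth_date")
  obs <- from_iso(rd("observation_periods"), c("obs_start", "obs_end"))
  de <- from_iso(rd("drug_exposures"), c("start", "end"))
  co <- from_iso(rd("condition_occurrences"), "day")
  tr <- rd("truth")
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  structure(list(
    persons = persons, observation_periods = obs,
    drug_exposures = de, condition_occurrences = co,
    truth = setNames(tr$true_log_rr, tr$drug_id),
    negative_controls = unlist(manifest$negative_controls),
    config = NULL
  ), class = "claims_dataset")
}
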