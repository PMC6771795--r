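# Dates are handled internally as integer days since 1970-01-01 (the R Date
# epoch); calendar arithmetic goes through the proleptic Gregorian calendar
# via the Date class.

as_day <- function(x) {
  if (inherits(x, "Date")) return(as.integer(x))
  if (is.character(x)) return(as.integer(as.Date(x)))
  as.integer(x)
}

day_to_date <- function(x) as.Date(x, origin = "1970-01-01")

#' Calendar-month lookup table covering a span of days
#'
#' @param first_day,last_day integer days (Date epoch) to cover.
#' @return data.table with one row per calendar month: `month_id` (sequential),
#'   `month_start`, `month_end` (integer days), `month_of_year` (1-12) and
#'   `mid` (midpoint day, used to evaluate age and season at month midpoints).
#' @keywords internal
month_table <- function(first_day, last_day) {
  d0 <- day_to_date(first_day)
  first_month <- as.Date(format(d0, "%Y-%m-01"))
  ms <- seq(first_month, day_to_date(last_day + 32L), by = "month")
  starts <- as.integer(ms)
  data.table(
    month_id = seq_along(starts[-length(starts)]),
    month_start = starts[-length(starts)],
    month_end = starts[-1L] - 1L,
    month_of_year = as.POSIXlt(ms[-length(ms)])$mon + 1L
  )[, mid := (month_start + month_end) / 2]
}

# day-of-year in [0, 1) for the seasonal sinusoid
year_fraction <- function(day) {
  lt <- as.POSIXlt(day_to_date(day))
  lt$yday / 365.25
}

age_years <- function(day, birth_day) (day - birth_day) / 365.25
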