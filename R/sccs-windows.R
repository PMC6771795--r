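#' Build exposed risk windows and pre-exposure windows from drug eras
#'
#' Each era yields a risk window from the day after era start through
#' `extension_days` after era end; overlapping windows of the same drug are
#' merged. A 30-day pre-exposure window precedes each era
#' (`[era_start - 30, era_start - 1]`) to absorb contraindication-driven
#' rate changes; pre-exposure time is clipped wherever it overlaps any risk
#' window (exposed status wins) and, when observation periods are supplied,
#' at the observation start.
#'
#' @param drug_eras eras of one drug from [build_drug_eras()].
#' @param extension_days 365 (simple-design variant) or 30 (nested-design
#'   variant).
#' @param pre_window_days length of the pre-exposure window (default 30).
#' @param observation_periods optional data.table (person_id, obs_start,
#'   obs_end) used to clip windows to observed time.
#' @return list with data.tables `risk` and `pre`, each
#'   (person_id, start, end).
#' @export
build_risk_windows <- function(drug_eras, extension_days,
                               pre_window_days = 30L,
                               observation_periods = NULL) {
  empty <- data.table(person_id = integer(), start = integer(),
                      end = integer())
  e <- as.data.table(drug_eras)
  if (!nrow(e)) return(list(risk = empty, pre = copy(empty)))
  risk <- merge_intervals(e[, .(person_id,
                                start = era_start + 1L,
                                end = era_end + as.integer(extension_days))])
  pre <- e[, .(person_id,
               start = era_start - as.integer(pre_window_days),
               end = era_start - 1L)]
  if (!is.null(observation_periods)) {
    op <- as.data.table(observation_periods)
    clip <- function(w) {
      w <- merge(w, op[, .(person_id, obs_start, obs_end)], by = "person_id")
      w[, start := pmax(start, obs_start)]
      w[, end := pmin(end, obs_end)]
      w[start <= end, .(person_id, start, end)]
    }
    risk <- clip(risk)
    pre <- clip(pre)
  }
  pre <- merge_intervals(interval_setdiff(pre, risk))
  list(risk = risk, pre = pre)
}

#' Partition observed time into SCCS analysis intervals
#'
#' For every person with at least one outcome event after the excluded
#' initial period, the remaining observation time is cut at every calendar
#' month boundary and every risk / pre-exposure window edge. Each interval
#' carries its length in days, its event count, exposure status
#' (exposed wins over pre-exposure), the calendar month, and age in months
#' evaluated at the calendar month midpoint (age and season are treated as
#' constant within a month). Persons whose only events fall in excluded
#' time contribute nothing and are dropped.
#'
#' @param observation_periods data.table (person_id, obs_start, obs_end).
#' @param events data.table (person_id, day) of outcome events.
#' @param windows list with `risk` and `pre` tables, from
#'   [build_risk_windows()].
#' @param birth_dates data.table (person_id, birth_date).
#' @param exclusion_days initial observation time excluded to establish
#'   exposure status at the start of follow-up (default 365).
#' @return data.table with one row per interval: person_id, start, end,
#'   days, events, exposed, pre_exposure, month_of_year, age_months.
#' @export
partition_observation <- function(observation_periods, events, windows,
                                  birth_dates, exclusion_days = 365L) {
  op <- as.data.table(observation_periods)
  ev <- as.data.table(events)
  op <- copy(op)[, included_start := obs_start + as.integer(exclusion_days)]
  op <- op[included_start <= obs_end]
  ev <- ev[op, on = .(person_id, day >= included_start, day <= obs_end),
           nomatch = 0L, .(person_id, day = x.day)]
  keep <- unique(ev$person_id)
  op <- op[person_id %in% keep]
  out_cols <- data.table(person_id = integer(), start = integer(),
                         end = integer(), days = integer(),
                         events = integer(), exposed = logical(),
                         pre_exposure = logical(), month_of_year = integer(),
                         age_months = numeric())
  if (!nrow(op)) return(out_cols)

  months <- month_table(min(op$included_start), max(op$obs_end))
  msb <- months$month_start - 1L   # candidate break days (end of prev month)

  ## breaks: included_start - 1, obs_end, month ends, window edges
  brk <- list(
    op[, .(person_id, b = included_start - 1L)],
    op[, .(person_id, b = obs_end)]
  )
  lo <- op$included_start - 1L
  hi <- op$obs_end
  i_lo <- findInterval(lo, msb) + 1L        # first month end  > lo
  i_hi <- findInterval(hi, msb)             # last month end  <= hi
  nmo <- pmax(0L, i_hi - i_lo + 1L)
  if (sum(nmo)) {
    brk$months <- data.table(
      person_id = rep(op$person_id, nmo),
      b = msb[unlist(lapply(which(nmo > 0L),
                            function(i) seq.int(i_lo[i], i_hi[i])))]
    )
  }
  for (w in windows[c("risk", "pre")]) {
    if (!is.null(w) && nrow(w)) {
      brk[[length(brk) + 1L]] <- w[, .(person_id, b = start - 1L)]
      brk[[length(brk) + 1L]] <- w[, .(person_id, b = end)]
    }
  }
  B <- rbindlist(brk)
  B <- merge(B, op[, .(person_id, included_start, obs_end)], by = "person_id")
  B <- B[b >= included_start - 1L & b <= obs_end]
  B <- unique(B[, .(person_id, b)])
  setorder(B, person_id, b)
  iv <- B[, .(start = head(b, -1L) + 1L, end = tail(b, -1L)),
          by = person_id]
  iv[, days := end - start + 1L]

  ## exposure labels: intervals never straddle a window edge, so the start
  ## day determines the status of the whole interval
  iv[, exposed := FALSE]
  iv[, pre_exposure := FALSE]
  if (nrow(windows$risk)) {
    hit <- iv[windows$risk, on = .(person_id, start >= start, start <= end),
              which = TRUE, nomatch = 0L]
    if (length(hit)) iv[unique(hit), exposed := TRUE]
  }
  if (nrow(windows$pre)) {
    hit <- iv[windows$pre, on = .(person_id, start >= start, start <= end),
              which = TRUE, nomatch = 0L]
    if (length(hit)) iv[unique(hit), pre_exposure := !exposed]
  }

  ## events per interval (intervals are disjoint day sets, so assignment is
  ## unambiguous)
  iv[, row_id := .I]
  iv[, events := 0L]
  cnt <- iv[ev, on = .(person_id, start <= day, end >= day),
            .(row_id = row_id), nomatch = 0L][, .N, by = row_id]
  if (nrow(cnt)) iv[cnt$row_id, events := cnt$N]

  ## month-of-year and age at month midpoint
  iv[, month_id := findInterval(start, months$month_start)]
  iv[, month_of_year := months$month_of_year[month_id]]
  iv <- merge(iv, as.data.table(birth_dates)[, .(person_id, birth_date)],
              by = "person_id", sort = FALSE)
  iv[, age_months := (months$mid[month_id] - birth_date) / 30.4375]
  setorder(iv, person_id, start)
  iv[, .(person_id, start, end, days, events, exposed, pre_exposure,
         month_of_year, age_months)]
}
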