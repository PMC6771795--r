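# Closed integer-day interval algebra used by era construction and the SCCS
# risk-window machinery. All tables carry person_id, start, end with
# start <= end; a day belongs to [start, end] inclusively.

# Merge overlapping or adjacent (gap 0) intervals per person.
merge_intervals <- function(x) {
  x <- as.data.table(x)
  if (!nrow(x)) return(x[, .(person_id, start, end)])
  x <- x[order(person_id, start, end)]
  x[, prev_end := shift(cummax(end)), by = person_id]
  x[, new_era := is.na(prev_end) | start > prev_end + 1L]
  x[, piece := cumsum(new_era), by = person_id]
  x[, .(start = min(start), end = max(end)), by = .(person_id, piece)][
    , .(person_id, start, end)]
}

# Set difference x \ y where the y intervals are disjoint per person.
interval_setdiff <- function(x, y) {
  x <- as.data.table(x)
  y <- as.data.table(y)
  if (!nrow(x) || !nrow(y)) return(x[, .(person_id, start, end)])
  x2 <- copy(x)[, xid := .I]
  setkey(y, person_id, start, end)
  ov <- foverlaps(x2, y,
                  by.x = c("person_id", "start", "end"),
                  type = "any", nomatch = NA)
  # rows of x with no overlap survive intact
  intact <- ov[is.na(start), .(person_id, start = i.start, end = i.end)]
  hit <- ov[!is.na(start)][order(xid, start)]
  pieces <- hit[, {
    xs <- i.start[1L]; xe <- i.end[1L]
    ps <- c(xs, end + 1L)
    pe <- c(start - 1L, xe)
    keep <- ps <= pe
    .(start = ps[keep], end = pe[keep])
  }, by = .(xid, person_id)][, .(person_id, start, end)]
  out <- rbind(intact, pieces)
  out[order(person_id, start)]
}
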