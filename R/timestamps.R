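# Timestamps are naive local wall-clock at minute precision, stored as
# POSIXct in UTC so that arithmetic is uniform (48 half-hour intervals per
# calendar day, no DST jumps).

#' Parse wall-clock timestamps
#'
#' Parses character timestamps into the package's internal representation:
#' naive local time at minute precision, carried as POSIXct in UTC so that
#' every day has exactly 48 half-hour intervals.
#'
#' @param x Character vector of timestamps.
#' @param format `strptime()` format string; default ISO-8601 to the minute.
#' @return POSIXct vector (UTC); unparseable elements become `NA`.
#' @export
parse_ts <- function(x, format = "%Y-%m-%d %H:%M") {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(as.character(x), tz = "UTC", format = format)
}

#' Format timestamps for CSV output
#'
#' @param x POSIXct vector.
#' @return Character vector, `"YYYY-MM-DD HH:MM"`; `NA` stays `NA`.
#' @export
format_ts <- function(x) {
  out <- format(x, "%Y-%m-%d %H:%M", tz = "UTC")
  out[is.na(x)] <- NA_character_
  out
}

# strictly-before count: number of elements of `sorted` (numeric, sorted)
# strictly less than each element of v; relies on minute precision so a
# 1-second shift cannot cross an event.
.count_before <- function(v, sorted) {
  findInterval(as.numeric(v) - 1, sorted)
}
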