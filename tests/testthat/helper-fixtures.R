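# Shared fixture builders: everything is generated in code.

ts0 <- function(s) parse_ts(s)

# quick visit-record frame from arrival/departure strings (plus optional
# surrogate timestamps)
make_visits <- function(arrival, departure, triage = NA, first_ews = NA,
                        last_ews = NA, ...) {
  n <- length(arrival)
  df <- data.frame(
    visit_id = sprintf("T%03d", seq_len(n)),
    arrival = parse_ts(arrival), departure = parse_ts(departure),
    triage_time = parse_ts(rep_len(triage, n)),
    first_ews_time = parse_ts(rep_len(first_ews, n)),
    last_ews_time = parse_ts(rep_len(last_ews, n)),
    age = rep(NA_real_, n), sex = rep(NA_character_, n),
    triage_score = rep(NA_integer_, n), trauma = rep(FALSE, n),
    diagnosis = rep(NA_character_, n), stringsAsFactors = FALSE)
  extra <- list(...)
  for (k in names(extra)) df[[k]] <- extra[[k]]
  df
}

parse_ts_vec <- function(x) if (all(is.na(x))) as.POSIXct(rep(NA, length(x))) else parse_ts(x)

# random record set fully inside [origin, origin + span_min): arrivals
# uniform, stays exponential, truncated so exits stay inside the grid
random_records <- function(n, origin, span_min, mean_los_min = 180) {
  origin <- parse_ts(origin)
  arr_off <- floor(runif(n) * (span_min - 1))
  los <- pmax(0, round(rexp(n, 1 / mean_los_min)))
  los <- pmin(los, span_min - 1 - arr_off)
  make_visits(origin + arr_off * 60, origin + (arr_off + los) * 60)
}

# shift-record frame for carry-over / risk tests: one op day per row set
make_shift_frame <- function(day, evening, night,
                             start_day = as.Date("2013-01-07"),
                             weekend = FALSE) {
  n <- length(day)
  data.frame(
    operational_day = rep(start_day + seq_len(n) - 1L, each = 3L),
    shift = factor(rep(c("day", "evening", "night"), n),
                   levels = c("day", "evening", "night")),
    weekend = weekend,
    max_queue = as.vector(rbind(day, evening, night)),
    n_intervals = 16L)
}

# interval frame with a given blackbox queue series
make_interval_frame <- function(grid, Q, A = 0L, D = 0L) {
  data.frame(interval_start = grid, A_blackbox = A, D_blackbox = D,
             Q_blackbox = Q)
}
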