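# Operational days and shifts: the day begins with the day shift at 07:00;
# shifts are day (07:00-14:59), evening (15:00-22:59) and night
# (23:00-06:59, attributed to the operational day on which the night
# began). Friday and Saturday nights count as weekend nights.

.shift_levels <- c("day", "evening", "night")

#' Map timestamps to operational day, shift and weekend flag
#'
#' @param ts POSIXct (or parseable character) timestamps.
#' @return Data.frame `(operational_day, shift, weekend)`: `operational_day`
#'   a `Date`; `shift` a factor day/evening/night; `weekend` `TRUE` for
#'   Saturday/Sunday day and evening shifts and for Friday/Saturday nights.
#' @export
shift_of <- function(ts) {
  ts <- parse_ts(ts)
  lt <- as.POSIXlt(ts, tz = "UTC")
  h <- lt$hour
  shift <- ifelse(h >= 7L & h < 15L, "day",
                  ifelse(h >= 15L & h < 23L, "evening", "night"))
  op_day <- as.Date(ts, tz = "UTC")
  op_day[shift == "night" & h < 7L] <- op_day[shift == "night" & h < 7L] - 1L
  wd <- as.integer(format(op_day, "%u"))  # 1 = Monday ... 7 = Sunday
  weekend <- ifelse(shift == "night", wd %in% c(5L, 6L), wd %in% c(6L, 7L))
  data.frame(operational_day = op_day,
             shift = factor(shift, levels = .shift_levels),
             weekend = weekend)
}

#' Per-shift maximum queue lengths with burn-in discard
#'
#' Splits the interval table into (operational day, shift) cells in
#' chronological order, discards the first `burn_in_shifts` cells (default
#' 3, i.e. the first 24 h, so the recursion started at `Q(0)=0` can reach
#' steady state), and records each remaining cell's maximum queue length.
#' A full shift holds 16 half-hour intervals; partial leading/trailing
#' shifts are kept and identifiable via `n_intervals < 16`. When a roster is
#' supplied, the majority-band nurse count and the patient-to-nurse ratio
#' at the maximum queue are attached, together with the alternative band's
#' figures (see [shift_nurses()]).
#'
#' @param intervals Interval table from [aggregate_table()] (ordered,
#'   contiguous).
#' @param qname Queue name; the table must carry column `Q_<qname>` (a bare
#'   `Q` column named `qname` is also accepted).
#' @param burn_in_shifts Number of leading shifts to discard, default 3.
#' @param roster Optional `ed_roster` for nurse counts and ratios.
#' @return Data.frame of shift records: `operational_day`, `shift`,
#'   `weekend`, `max_queue`, `n_intervals`, `n_arrivals` (when the `A`
#'   column exists) and, with a roster, `n_nurses`, `ratio`,
#'   `n_nurses_alt`, `ratio_alt`.
#' @export
max_queue_per_shift <- function(intervals, qname = "blackbox",
                                burn_in_shifts = 3L, roster = NULL) {
  if (!nrow(intervals)) return(intervals[0, ])
  qcol <- if (paste0("Q_", qname) %in% names(intervals)) paste0("Q_", qname)
          else if (qname %in% names(intervals)) qname
          else stop("no queue column for '", qname, "' in interval table")
  acol <- if (paste0("A_", qname) %in% names(intervals)) paste0("A_", qname)
          else NA_character_
  o <- order(intervals$interval_start)
  iv <- intervals[o, , drop = FALSE]
  sh <- shift_of(iv$interval_start)
  key <- paste(sh$operational_day, sh$shift)
  cell <- cumsum(c(TRUE, key[-1] != key[-length(key)]))  # chronological cells
  first <- !duplicated(cell)
  rec <- data.frame(
    operational_day = sh$operational_day[first],
    shift = sh$shift[first],
    weekend = sh$weekend[first],
    max_queue = as.integer(tapply(iv[[qcol]], cell, max)),
    n_intervals = as.integer(tapply(cell, cell, length)))
  if (!is.na(acol))
    rec$n_arrivals <- as.integer(tapply(iv[[acol]], cell, sum))
  burn_in_shifts <- as.integer(burn_in_shifts)
  if (burn_in_shifts > 0L) rec <- rec[-seq_len(min(burn_in_shifts, nrow(rec))), ,
                                      drop = FALSE]
  rownames(rec) <- NULL
  if (!is.null(roster)) {
    combos <- unique(rec[, c("shift", "weekend")])
    rec$n_nurses <- NA_integer_; rec$n_nurses_alt <- NA_integer_
    for (i in seq_len(nrow(combos))) {
      nn <- shift_nurses(roster, as.character(combos$shift[i]), combos$weekend[i])
      sel <- rec$shift == combos$shift[i] & rec$weekend == combos$weekend[i]
      rec$n_nurses[sel] <- nn$primary
      rec$n_nurses_alt[sel] <- nn$alternative
    }
    rec$ratio <- patient_nurse_ratio(rec$max_queue, rec$n_nurses)
    rec$ratio_alt <- ifelse(is.na(rec$n_nurses_alt), NA_real_,
                            patient_nurse_ratio(rec$max_queue,
                                                ifelse(is.na(rec$n_nurses_alt), 1L,
                                                       rec$n_nurses_alt)))
  }
  rec
}

# half-away-from-zero rounding to `digits` decimals (base round() is
# banker's rounding, which would give 2.857 -> 2.9 but 1.75 -> 1.8 only by
# accident of binary representation)
.round_half_away <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Patient-to-nurse ratio
#'
#' Queue length divided by on-duty nurses, rounded half-away-from-zero to
#' one decimal (20/7 -> 2.9, 7/4 -> 1.8).
#'
#' @param queue_len Non-negative integer queue length(s).
#' @param n_nurses Positive integer nurse count(s).
#' @return Numeric ratio(s), one decimal.
#' @export
patient_nurse_ratio <- function(queue_len, n_nurses) {
  if (any(!is.na(n_nurses) & n_nurses < 1)) stop("n_nurses must be >= 1")
  .round_half_away(queue_len / n_nurses, 1L)
}

#' Summarise per-shift maximum queues by stratum
#'
#' Groups shift records by shift and weekday/weekend (and optionally
#' season) and reports, per stratum: the number of shifts, min, max, median
#' and IQR of the maximum queue (linear-interpolation quantiles, so an IQR
#' of 4.25 on integer data is possible), and the share of shifts whose
#' maximum reached or exceeded `capacity`, as a percentage. Strata with no
#' shifts yield an all-missing row.
#'
#' @param shift_records Output of [max_queue_per_shift()].
#' @param capacity Bed capacity threshold (e.g. `roster$bed_capacity`).
#' @param by_season Also stratify by season (summer = April-September)?
#' @return Data.frame, one row per stratum.
#' @export
summarize_max_queues <- function(shift_records, capacity, by_season = FALSE) {
  strata <- list(shift = factor(.shift_levels, levels = .shift_levels),
                 weekend = c(FALSE, TRUE))
  if (by_season) strata$season <- c("summer", "winter")
  grid <- expand.grid(strata, stringsAsFactors = FALSE)
  if (by_season)
    shift_records$season <- season_of(shift_records$operational_day)
  out <- grid
  out$n_shifts <- 0L
  out$min <- out$max <- out$median <- out$iqr <- out$pct_ge_capacity <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sel <- shift_records$shift == grid$shift[i] &
      shift_records$weekend == grid$weekend[i]
    if (by_season) sel <- sel & shift_records$season == grid$season[i]
    v <- shift_records$max_queue[sel]
    out$n_shifts[i] <- length(v)
    if (length(v)) {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      out$min[i] <- min(v); out$max[i] <- max(v)
      out$median[i] <- q[2]; out$iqr[i] <- q[3] - q[1]
      out$pct_ge_capacity[i] <- 100 * mean(v >= capacity)
    }
  }
  out
}
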