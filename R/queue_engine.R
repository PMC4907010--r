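# The queueing core: interval grid, event counting per queue definition,
# the queue-length recursion Q(t+1) = Q(t) + A(t) - D(t), a direct-census
# oracle, the aggregated interval table, and flow-completeness
# classification.

#' Define a queue by an entry and an exit timestamp field
#'
#' A queue is the set of patients between two milestones of the visit. The
#' black-box queue uses arrival and departure only; the extended model
#' splits the stay into four sub-queues bounded by the surrogate markers
#' (triage, first and last early-warning-score assessment).
#'
#' @param name Queue name.
#' @param entry_field,exit_field One of `"arrival"`, `"triage_time"`,
#'   `"first_ews_time"`, `"last_ews_time"`, `"departure"`; entry must
#'   precede exit in that idealised order.
#' @return An `ed_queue_def`.
#' @export
queue_definition <- function(name, entry_field, exit_field) {
  entry_field <- match.arg(entry_field, .ts_fields)
  exit_field <- match.arg(exit_field, .ts_fields)
  if (match(entry_field, .ts_fields) >= match(exit_field, .ts_fields))
    stop("entry_field must precede exit_field in the idealised order ",
         paste(.ts_fields, collapse = " <= "))
  structure(list(name = name, entry_field = entry_field,
                 exit_field = exit_field), class = "ed_queue_def")
}

#' Built-in queue definitions
#'
#' `blackbox` = arrival to departure; `Q1` = arrival to triage (waiting on
#' initial assessment); `Q2` = triage to first EWS (waiting on a doctor);
#' `Q3` = first to last EWS (under examination/treatment); `Q4` = last EWS
#' to departure (waiting to leave).
#'
#' @param which Character vector of names to return, default all five.
#' @return Named list of `ed_queue_def`s.
#' @export
builtin_queues <- function(which = c("blackbox", "Q1", "Q2", "Q3", "Q4")) {
  all <- list(
    blackbox = queue_definition("blackbox", "arrival", "departure"),
    Q1 = queue_definition("Q1", "arrival", "triage_time"),
    Q2 = queue_definition("Q2", "triage_time", "first_ews_time"),
    Q3 = queue_definition("Q3", "first_ews_time", "last_ews_time"),
    Q4 = queue_definition("Q4", "last_ews_time", "departure"))
  which <- match.arg(which, names(all), several.ok = TRUE)
  all[which]
}

#' Build the interval grid
#'
#' Tiles `[period_start, period_end)` with half-open intervals
#' `[s, s + width)`. 365 days at the default 30-min width give 17,520
#' intervals.
#'
#' @param period_start,period_end POSIXct (or parseable character) bounds.
#' @param width_min Interval width in minutes; must be positive and divide
#'   24 h evenly.
#' @return POSIXct vector of interval starts with attribute `width_min`.
#' @export
make_interval_grid <- function(period_start, period_end, width_min = 30) {
  period_start <- parse_ts(period_start)
  period_end <- parse_ts(period_end)
  if (is.na(period_start) || is.na(period_end)) stop("unparseable period bound")
  if (period_start >= period_end) stop("period_start must precede period_end")
  width_min <- as.numeric(width_min)
  if (!is.finite(width_min) || width_min <= 0) stop("width must be positive")
  if (1440 %% width_min != 0) stop("width must divide 24 h evenly")
  n <- ceiling(as.numeric(difftime(period_end, period_start, units = "mins")) /
                 width_min)
  grid <- period_start + (seq_len(n) - 1) * width_min * 60
  attr(grid, "width_min") <- width_min
  grid
}

.grid_width <- function(grid) {
  w <- attr(grid, "width_min")
  if (is.null(w)) w <- as.numeric(difftime(grid[2], grid[1], units = "mins"))
  w
}

# records usable for a queue: both bounds present and entry <= exit
# (order-violating records are excluded from this queue only)
.queue_events <- function(records, qdef) {
  entry <- records[[qdef$entry_field]]
  exit <- records[[qdef$exit_field]]
  ok <- !is.na(entry) & !is.na(exit) & entry <= exit
  list(entry = entry[ok], exit = exit[ok])
}

.bin_counts <- function(times, grid, width_sec) {
  g0 <- as.numeric(grid[1])
  gN <- as.numeric(grid[length(grid)]) + width_sec
  x <- as.numeric(times)
  inside <- x >= g0 & x < gN
  idx <- floor((x[inside] - g0) / width_sec) + 1
  list(counts = tabulate(idx, nbins = length(grid)),
       spill = sum(!inside))
}

#' Count arrivals and departures per interval for one queue
#'
#' An event at time `x` is counted in the unique interval with
#' `start <= x < start + width` (boundary events belong to the interval
#' starting there). Records missing either bound of the queue -- or
#' violating its order -- contribute nothing to it. Events outside the grid
#' are ignored and tallied in the `spill` attribute.
#'
#' @param records Validated visit records.
#' @param grid Interval grid from [make_interval_grid()].
#' @param qdef An `ed_queue_def`.
#' @return Data.frame `(interval_start, A, D)` with attribute `spill`
#'   (`c(A = entries outside grid, D = exits outside grid)`).
#' @export
count_events <- function(records, grid, qdef = builtin_queues("blackbox")[[1]]) {
  if (!length(grid)) stop("grid must be non-empty")
  w <- .grid_width(grid) * 60
  ev <- .queue_events(records, qdef)
  a <- .bin_counts(ev$entry, grid, w)
  d <- .bin_counts(ev$exit, grid, w)
  out <- data.frame(interval_start = grid, A = a$counts, D = d$counts)
  attr(out, "spill") <- c(A = a$spill, D = d$spill)
  out
}

#' The queue-length recursion
#'
#' Computes `Q(t+1) = Q(t) + A(t) - D(t)` from per-interval arrival and
#' departure counts, starting at `Q(0) = q0`, in exact integer arithmetic.
#' `Q[t]` is the queue at the *start* of interval `t`; the returned series
#' has one more element than `A`, the last being the queue at period end.
#' Negative values (possible when patients present before the period start
#' depart inside it) are returned unchanged with a warning -- clamping would
#' silently break conservation.
#'
#' @param A,D Integer count series of equal length.
#' @param q0 Initial queue length, default 0.
#' @return Integer vector of length `length(A) + 1`.
#' @export
queue_recursion <- function(A, D, q0 = 0L) {
  if (length(A) != length(D)) stop("A and D must have equal length")
  Q <- c(as.integer(q0), as.integer(q0) + cumsum(as.integer(A) - as.integer(D)))
  if (any(Q < 0L))
    warning("negative queue length: patients present before the period ",
            "start are invisible under Q(0)=0; consider a burn-in discard")
  Q
}

#' Direct-census oracle for queue lengths
#'
#' Recounts, for every interval start `s`, the patients present in the
#' queue: `entry < s` and `exit >= s`. This matches the recursion's timing
#' exactly (an event on a boundary belongs to the interval starting there,
#' so it is reflected in the census one interval later): for any record set
#' whose events all fall inside the grid,
#' `census_oracle == queue_recursion(count_events(...))[1:n]` elementwise.
#' Kept deliberately independent of the recursion as a verification path.
#'
#' @inheritParams count_events
#' @return Integer vector of queue lengths at each interval start.
#' @export
census_oracle <- function(records, grid, qdef = builtin_queues("blackbox")[[1]]) {
  ev <- .queue_events(records, qdef)
  entry_s <- sort(as.numeric(ev$entry))
  exit_s <- sort(as.numeric(ev$exit))
  .count_before(grid, entry_s) - .count_before(grid, exit_s)
}

#' Build the aggregated interval table
#'
#' One row per grid interval carrying, for each queue definition, the
#' arrival count `A_<name>`, departure count `D_<name>` and start-of-interval
#' queue length `Q_<name>` (from the recursion with `Q(0)=0`), plus
#' attribute summaries over patients present in the black-box queue at the
#' interval start: `mean_age`, `n_red` (triaged red, score 1) and
#' `n_trauma`.
#'
#' @param records Validated visit records.
#' @param grid Interval grid.
#' @param qdefs List of `ed_queue_def`s, default all five built-ins.
#' @return Data.frame with attributes `spill` (per-queue event spill counts)
#'   and `final_Q` (queue at period end per queue).
#' @export
aggregate_table <- function(records, grid, qdefs = builtin_queues()) {
  if (!length(qdefs)) stop("qdefs must be non-empty")
  out <- data.frame(interval_start = grid)
  spill <- list()
  finalQ <- list()
  for (qd in qdefs) {
    cnt <- count_events(records, grid, qd)
    Q <- suppressWarnings(queue_recursion(cnt$A, cnt$D))
    if (any(Q < 0L))
      warning("negative queue lengths in queue '", qd$name,
              "': patients present before the period start are invisible ",
              "under Q(0)=0", call. = FALSE)
    out[[paste0("A_", qd$name)]] <- cnt$A
    out[[paste0("D_", qd$name)]] <- cnt$D
    out[[paste0("Q_", qd$name)]] <- Q[seq_along(grid)]
    spill[[qd$name]] <- attr(cnt, "spill")
    finalQ[[qd$name]] <- Q[length(Q)]
  }

  # attribute summaries over patients present (black-box) at interval start
  bb <- .queue_events(records, builtin_queues("blackbox")[[1]])
  keep <- !is.na(records$arrival) & !is.na(records$departure) &
    records$arrival <= records$departure
  r <- records[keep, , drop = FALSE]
  ord_a <- order(r$arrival)
  ord_d <- order(r$departure)
  before_a <- .count_before(grid, as.numeric(r$arrival)[ord_a])
  before_d <- .count_before(grid, as.numeric(r$departure)[ord_d])
  present <- before_a - before_d
  csum <- function(v, ord, before) {
    cs <- c(0, cumsum(ifelse(is.na(v[ord]), 0, v[ord])))
    cnt <- c(0, cumsum(!is.na(v[ord])))
    list(sum = cs[before + 1], n = cnt[before + 1])
  }
  age_a <- csum(r$age, ord_a, before_a); age_d <- csum(r$age, ord_d, before_d)
  n_age <- age_a$n - age_d$n
  out$mean_age <- ifelse(n_age > 0, (age_a$sum - age_d$sum) / n_age, NA_real_)
  red <- as.numeric(!is.na(r$triage_score) & r$triage_score == 1L)
  out$n_red <- csum(red, ord_a, before_a)$sum - csum(red, ord_d, before_d)$sum
  tra <- as.numeric(isTRUE_vec(r$trauma))
  out$n_trauma <- csum(tra, ord_a, before_a)$sum - csum(tra, ord_d, before_d)$sum
  out$n_red <- as.integer(round(out$n_red))
  out$n_trauma <- as.integer(round(out$n_trauma))

  attr(out, "spill") <- spill
  attr(out, "final_Q") <- finalQ
  attr(out, "width_min") <- .grid_width(grid)
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Write / read the aggregated interval table
#'
#' CSV with ISO-8601 interval starts and integer counts; round-trips with
#' [read_intervals()].
#'
#' @param intervals Output of [aggregate_table()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  out <- intervals
  out$interval_start <- format_ts(out$interval_start)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"interval_start" %in% names(df))
    stop("interval table lacks column 'interval_start'")
  df$interval_start <- parse_ts(df$interval_start)
  df
}

#' Classify flow completeness of visit records
#'
#' Assigns each record exactly one category by presence of the surrogate
#' timestamps: `complete` (triage, first and last EWS all present),
#' `triage_only` (triage present but the EWS chain incomplete),
#' `ews_no_triage` (first EWS without triage), `blackbox_only` (neither
#' triage nor first EWS). Categories are exhaustive and mutually exclusive;
#' the marginal share of triaged patients is `complete + triage_only`.
#'
#' @param records Validated visit records.
#' @return An `ed_flow_completeness`: counts, total, and percentages to one
#'   decimal.
#' @export
classify_flow <- function(records) {
  tri <- !is.na(records$triage_time)
  few <- !is.na(records$first_ews_time)
  lew <- !is.na(records$last_ews_time)
  complete <- tri & few & lew
  counts <- c(
    complete = sum(complete),
    triage_only = sum(tri & !complete),
    ews_no_triage = sum(!tri & few),
    blackbox_only = sum(!tri & !few))
  total <- nrow(records)
  stopifnot(sum(counts) == total)
  pct <- round(100 * counts / total, 1)
  structure(list(counts = counts, total = total, pct = pct,
                 pct_triaged = round(100 * (counts[["complete"]] +
                                              counts[["triage_only"]]) / total, 1)),
            class = "ed_flow_completeness")
}

#' @export
print.ed_flow_completeness <- function(x, ...) {
  cat(sprintf("Flow completeness of %d visits:\n", x$total))
  for (k in names(x$counts))
    cat(sprintf("  %-14s %6d (%.1f%%)\n", k, x$counts[[k]], x$pct[[k]]))
  cat(sprintf("  %-14s %6d (%.1f%%)\n", "triaged",
              x$counts[["complete"]] + x$counts[["triage_only"]],
              x$pct_triaged))
  invisible(x)
}
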