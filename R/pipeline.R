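# Pipeline entry points: simulate -> aggregate -> analyze, each writing
# its outputs plus a run manifest. A thin command-line front-end over
# these lives in inst/cli/edcrowd.R.

.write_manifest <- function(path, command, inputs = character(),
                            config = list(), seed = NULL) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    command = command,
    input_digests = digests,
    config = config,
    package_version = as.character(utils::packageVersion("edcrowd")),
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    seed = seed)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate visits and write them to CSV
#'
#' @param spec An `ed_sim_spec`, or the path of a YAML spec for
#'   [read_sim_spec()].
#' @param out_csv Output visits CSV.
#' @param seed Optional seed overriding the spec's.
#' @return The simulated records, invisibly; writes `out_csv` and
#'   `<out_csv>.manifest.json`.
#' @export
run_simulate <- function(spec, out_csv, seed = NULL) {
  spec_path <- NULL
  if (is.character(spec)) { spec_path <- spec; spec <- read_sim_spec(spec) }
  stopifnot(inherits(spec, "ed_sim_spec"))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  rec <- simulate_ed(spec)
  write_patients(rec, out_csv)
  .write_manifest(paste0(out_csv, ".manifest.json"), "simulate",
                  inputs = c(spec_path, out_csv),
                  config = list(period_start = format_ts(spec$period_start),
                                period_end = format_ts(spec$period_end),
                                count_model = spec$count_model),
                  seed = spec$seed)
  message(sprintf("simulated %d visits -> %s", nrow(rec), out_csv))
  invisible(rec)
}

#' Aggregate a visits CSV into the 30-min interval table
#'
#' Reads and validates visits, builds the interval grid over the requested
#' period (default: whole calendar days spanning the data), counts
#' arrivals/departures and runs the queue recursion for each requested
#' queue, and writes the interval table, the validation report (JSON) and
#' a manifest.
#'
#' @param visits_csv Input visits CSV.
#' @param out_csv Output interval-table CSV.
#' @param period_start,period_end Optional period bounds; defaults cover
#'   the data rounded out to whole days.
#' @param width_min Interval width, default 30.
#' @param queues Character vector of built-in queue names, default all.
#' @param column_map,timestamp_format Passed to [read_patients()].
#' @return The interval table, invisibly.
#' @export
run_aggregate <- function(visits_csv, out_csv, period_start = NULL,
                          period_end = NULL, width_min = 30,
                          queues = c("blackbox", "Q1", "Q2", "Q3", "Q4"),
                          column_map = NULL,
                          timestamp_format = "%Y-%m-%d %H:%M") {
  rp <- read_patients(visits_csv, column_map = column_map,
                      timestamp_format = timestamp_format)
  rec <- rp$records
  if (rp$report$n_dropped > 0L)
    message(sprintf("dropped %d of %d records (see validation report)",
                    rp$report$n_dropped, rp$report$n_read))
  if (is.null(period_start))
    period_start <- if (nrow(rec)) as.POSIXct(trunc(min(rec$arrival), "days")) else
      stop("empty visits file and no explicit period given")
  if (is.null(period_end))
    period_end <- as.POSIXct(trunc(max(rec$departure), "days")) + 86400
  grid <- make_interval_grid(period_start, period_end, width_min)
  iv <- aggregate_table(rec, grid, builtin_queues(queues))
  write_intervals(iv, out_csv)
  report_path <- paste0(out_csv, ".validation.json")
  jsonlite::write_json(
    list(n_read = rp$report$n_read, n_accepted = rp$report$n_accepted,
         n_dropped = rp$report$n_dropped,
         violations = rp$report$violations,
         spill = attr(iv, "spill")),
    report_path, auto_unbox = TRUE, pretty = TRUE)
  .write_manifest(paste0(out_csv, ".manifest.json"), "aggregate",
                  inputs = c(visits_csv, out_csv),
                  config = list(width_min = width_min, queues = queues))
  message(sprintf("aggregated %d records into %d intervals -> %s",
                  nrow(rec), nrow(iv), out_csv))
  invisible(iv)
}

#' Analyse an interval table: shifts, risk, carry-over, dispersion
#'
#' Extracts per-shift maximum queues (with burn-in), summarises them by
#' stratum, computes capacity-exceedance risks, carry-over correlations,
#' Kruskal-Wallis comparisons across shifts and day classes, and Fisher's
#' dispersion index of the per-interval arrival counts. Writes one CSV per
#' result plus a manifest.
#'
#' @param intervals Interval table (data.frame) or path of a CSV written by
#'   [write_intervals()].
#' @param roster An `ed_roster` or the path of a roster config file.
#' @param out_dir Output directory (created if needed).
#' @param qname Queue to analyse, default `"blackbox"`.
#' @param burn_in Leading shifts to discard, default 3.
#' @param capacity Exceedance threshold; default the roster's bed capacity.
#' @param by_season Stratify summaries and risks by season?
#' @return List with `shifts`, `summary`, `risk`, `carry_over`, `stats`,
#'   invisibly.
#' @export
run_analyze <- function(intervals, roster, out_dir, qname = "blackbox",
                        burn_in = 3L, capacity = NULL, by_season = FALSE) {
  if (is.character(intervals)) intervals <- read_intervals(intervals)
  if (is.character(roster)) roster <- read_roster(roster)
  stopifnot(inherits(roster, "ed_roster"))
  if (is.null(capacity)) capacity <- roster$bed_capacity
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  shifts <- max_queue_per_shift(intervals, qname = qname,
                                burn_in_shifts = burn_in, roster = roster)
  summ <- summarize_max_queues(shifts, capacity, by_season = by_season)
  risk <- exceedance_risk(shifts, capacity, by_season = by_season)

  pairings <- c("day_to_evening", "evening_to_night", "night_to_day",
                "day_to_next_day")
  if ("n_arrivals" %in% names(shifts)) pairings <- c(pairings, "day_arrivals")
  co <- do.call(rbind, lapply(pairings, function(p) {
    r <- carry_over(shifts, p)
    data.frame(pairing = p, rho = r$rho, p_value = r$p_value,
               n_pairs = r$n_pairs, stringsAsFactors = FALSE)
  }))

  kw_shift <- kruskal_wallis(split(shifts$max_queue, shifts$shift))
  kw_weekend <- kruskal_wallis(split(shifts$max_queue, shifts$weekend))
  acol <- if (paste0("A_", qname) %in% names(intervals)) paste0("A_", qname)
          else "A"
  disp <- fisher_dispersion(intervals[[acol]])
  stats_tab <- data.frame(
    analysis = c("kruskal_wallis_shifts", "kruskal_wallis_weekend",
                 "fisher_dispersion_arrivals"),
    statistic = c(kw_shift$H, kw_weekend$H, disp$index),
    p_value = c(kw_shift$p_value, kw_weekend$p_value, disp$p_value),
    n = c(nrow(shifts), nrow(shifts), disp$n),
    stringsAsFactors = FALSE)

  paths <- file.path(out_dir, c("shifts.csv", "summary.csv", "risk.csv",
                                "carryover.csv", "stats.csv"))
  utils::write.csv(shifts, paths[1], row.names = FALSE, na = "")
  utils::write.csv(summ, paths[2], row.names = FALSE, na = "")
  utils::write.csv(risk, paths[3], row.names = FALSE, na = "")
  utils::write.csv(co, paths[4], row.names = FALSE, na = "")
  utils::write.csv(stats_tab, paths[5], row.names = FALSE, na = "")
  .write_manifest(file.path(out_dir, "manifest.json"), "analyze",
                  inputs = paths,
                  config = list(qname = qname, burn_in = burn_in,
                                capacity = capacity, by_season = by_season))
  message(sprintf("analysis of %d shift records -> %s", nrow(shifts), out_dir))
  invisible(list(shifts = shifts, summary = summ, risk = risk,
                 carry_over = co, stats = stats_tab))
}
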