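# Duty-roster / capacity configuration: bed capacity plus nurse counts per
# clock-time band, separately for weekdays and weekends.

.parse_clock <- function(x) {
  # "HH:MM" -> minute of day
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("invalid clock time: ", paste(x[bad], collapse = ", "))
  h <- as.integer(vapply(m, `[`, "", 2L))
  mi <- as.integer(vapply(m, `[`, "", 3L))
  if (any(h > 23L | mi > 59L)) stop("invalid clock time: out of range")
  h * 60L + mi
}

#' Construct and validate a roster/capacity configuration
#'
#' A roster holds the ED's bed capacity and the on-duty nurse count per
#' clock-time band. Bands are inclusive of both endpoints at minute
#' resolution (a band ending `"11:59"` hands over to one starting `"12:00"`)
#' and may wrap past midnight (`"23:00"`--`"06:59"`). Within each day class
#' (`weekday`, `weekend`) the bands must cover 24 h without overlap.
#'
#' @param bed_capacity Positive integer number of ED beds.
#' @param nurse_bands Data.frame with columns `day_class`
#'   (`"weekday"`/`"weekend"`), `start`, `end` (`"HH:MM"`), `nurses`
#'   (positive integer).
#' @return An `ed_roster` object.
#' @export
roster_config <- function(bed_capacity, nurse_bands) {
  bed_capacity <- as.integer(bed_capacity)
  if (is.na(bed_capacity) || bed_capacity < 1L)
    stop("bed_capacity must be a positive integer")
  nb <- as.data.frame(nurse_bands, stringsAsFactors = FALSE)
  need <- c("day_class", "start", "end", "nurses")
  if (!all(need %in% names(nb)))
    stop("nurse_bands needs columns: ", paste(need, collapse = ", "))
  if (!all(nb$day_class %in% c("weekday", "weekend")))
    stop("day_class must be 'weekday' or 'weekend'")
  nb$nurses <- as.integer(nb$nurses)
  if (any(is.na(nb$nurses) | nb$nurses < 1L))
    stop("nurse counts must be positive integers")
  nb$start_min <- .parse_clock(nb$start)
  nb$end_min <- .parse_clock(nb$end)

  for (cls in c("weekday", "weekend")) {
    b <- nb[nb$day_class == cls, , drop = FALSE]
    if (!nrow(b)) stop("no nurse bands for day class '", cls, "'")
    cover <- integer(1440L)
    for (i in seq_len(nrow(b))) {
      mins <- if (b$start_min[i] <= b$end_min[i])
        b$start_min[i]:b$end_min[i]
      else  # wraps midnight
        c(b$start_min[i]:1439L, 0L:b$end_min[i])
      cover[mins + 1L] <- cover[mins + 1L] + 1L
    }
    if (any(cover > 1L)) {
      m <- which(cover > 1L)[1L] - 1L
      stop(sprintf("%s bands overlap at %02d:%02d", cls, m %/% 60L, m %% 60L))
    }
    if (any(cover == 0L)) {
      m <- which(cover == 0L)[1L] - 1L
      stop(sprintf("%s bands leave %02d:%02d uncovered", cls, m %/% 60L, m %% 60L))
    }
  }
  structure(list(bed_capacity = bed_capacity, nurse_bands = nb),
            class = "ed_roster")
}

#' Read a roster configuration from YAML or JSON
#'
#' The file declares `bed_capacity` and a `nurse_bands` list of
#' `{day_class, start, end, nurses}` entries; see [roster_config()] for the
#' validation rules.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return An `ed_roster`.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop("roster file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$bed_capacity)) stop("roster config must declare bed_capacity")
  if (is.null(cfg$nurse_bands)) stop("roster config must declare nurse_bands")
  nb <- cfg$nurse_bands
  if (!is.data.frame(nb))
    nb <- do.call(rbind, lapply(nb, function(b)
      data.frame(day_class = b$day_class, start = b$start, end = b$end,
                 nurses = b$nurses, stringsAsFactors = FALSE)))
  roster_config(cfg$bed_capacity, nb)
}

#' Default roster: a 19-bed Danish university-hospital ED
#'
#' The bundled reference configuration: 19 beds; weekday nurse bands
#' 07:00-11:59 (7), 12:00-19:59 (8), 20:00-22:59 (7), 23:00-06:59 (4);
#' weekend bands 07:00-10:59 (7), 11:00-19:59 (8), 20:00-22:59 (7),
#' 23:00-06:59 (5). Friday and Saturday nights are handled as weekend
#' nights by the shift logic, not by the roster itself.
#'
#' @return An `ed_roster`.
#' @export
default_roster <- function() {
  bands <- data.frame(
    day_class = c(rep("weekday", 4), rep("weekend", 4)),
    start = c("07:00", "12:00", "20:00", "23:00",
              "07:00", "11:00", "20:00", "23:00"),
    end   = c("11:59", "19:59", "22:59", "06:59",
              "10:59", "19:59", "22:59", "06:59"),
    nurses = c(7L, 8L, 7L, 4L, 7L, 8L, 7L, 5L),
    stringsAsFactors = FALSE)
  roster_config(19L, bands)
}

#' @export
print.ed_roster <- function(x, ...) {
  cat(sprintf("ED roster: %d beds\n", x$bed_capacity))
  nb <- x$nurse_bands
  for (i in seq_len(nrow(nb)))
    cat(sprintf("  %-7s %s-%s: %d nurses\n",
                nb$day_class[i], nb$start[i], nb$end[i], nb$nurses[i]))
  invisible(x)
}

.nurses_at_minute <- function(roster, minute_of_day, day_class) {
  nb <- roster$nurse_bands
  out <- rep(NA_integer_, length(minute_of_day))
  for (cls in unique(day_class)) {
    b <- nb[nb$day_class == cls, , drop = FALSE]
    idx <- which(day_class == cls)
    for (i in seq_len(nrow(b))) {
      inb <- if (b$start_min[i] <= b$end_min[i])
        minute_of_day[idx] >= b$start_min[i] & minute_of_day[idx] <= b$end_min[i]
      else
        minute_of_day[idx] >= b$start_min[i] | minute_of_day[idx] <= b$end_min[i]
      out[idx[inb]] <- b$nurses[i]
    }
  }
  out
}

#' Nurses on duty at a point in time
#'
#' Looks up the roster band covering each timestamp. The day class follows
#' the operational shift logic: Friday and Saturday nights use the weekend
#' roster, and the night band of (say) Monday 02:00 belongs to the Sunday
#' operational day but still draws weekday staffing because Sunday night
#' (ending Monday morning) is a weekday night.
#'
#' @param roster An `ed_roster`.
#' @param ts POSIXct timestamps.
#' @return Integer vector of nurse counts.
#' @export
nurses_on_duty <- function(roster, ts) {
  ts <- parse_ts(ts)
  sh <- shift_of(ts)
  lt <- as.POSIXlt(ts, tz = "UTC")
  mod <- lt$hour * 60L + lt$min
  cls <- ifelse(sh$weekend, "weekend", "weekday")
  .nurses_at_minute(roster, mod, cls)
}

#' Nurse count attributed to a whole shift
#'
#' A shift can straddle two roster bands (the weekday day shift 07:00-15:00
#' spans the 7-nurse morning band and the 8-nurse midday band). The shift is
#' attributed the count of the band covering the majority of its 8 hours;
#' ties go to the band in force at the start of the shift. The alternative
#' count (the other band's staffing, when one exists) is returned alongside
#' so ratios can be reported under both, mirroring how sites quote
#' "2.5 when 8 nurses" style alternatives.
#'
#' @param roster An `ed_roster`.
#' @param shift `"day"`, `"evening"` or `"night"`.
#' @param weekend Logical: does this shift run on the weekend roster?
#' @return List with `primary` and `alternative` (NA if the shift sits in a
#'   single band) nurse counts.
#' @export
shift_nurses <- function(roster, shift, weekend) {
  shift <- match.arg(shift, c("day", "evening", "night"))
  win <- switch(shift,
                day = 7L * 60L + 0L:(8L * 60L - 1L),
                evening = 15L * 60L + 0L:(8L * 60L - 1L),
                night = (23L * 60L + 0L:(8L * 60L - 1L)) %% 1440L)
  cls <- if (weekend) "weekend" else "weekday"
  counts <- .nurses_at_minute(roster, win, rep(cls, length(win)))
  tab <- table(counts)
  lv <- as.integer(names(tab))
  mx <- max(tab)
  top <- lv[tab == mx]
  primary <- if (length(top) == 1L) top else counts[1L]  # tie: band at shift start
  alt <- lv[lv != primary]
  alternative <- if (length(alt)) alt[which.max(tab[as.character(alt)])] else NA_integer_
  list(primary = as.integer(primary), alternative = as.integer(alternative))
}
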