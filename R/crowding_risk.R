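# Empirical-CDF crowding risk: the probability that a shift's maximum
# queue reaches or exceeds bed capacity at least once during the shift,
# stratified by shift, day class and season.

#' Empirical cumulative distribution function of queue maxima
#'
#' Thin wrapper over [stats::ecdf()] with an explicit empty-input error:
#' returns the right-continuous step function `F(x)` = share of values
#' `<= x`, with `F(max) = 1`.
#'
#' @param values Non-empty numeric vector (typically per-shift maxima).
#' @return A function of class `ecdf`.
#' @export
queue_ecdf <- function(values) {
  if (!length(values) || all(is.na(values)))
    stop("ecdf of an empty value set is undefined")
  stats::ecdf(values[!is.na(values)])
}

#' Season of a date
#'
#' Summer runs April 1 through September 30; everything else is winter.
#'
#' @param d `Date` vector (or parseable character).
#' @return Character vector, `"summer"` or `"winter"`.
#' @export
season_of <- function(d) {
  m <- as.integer(format(as.Date(d), "%m"))
  ifelse(m >= 4L & m <= 9L, "summer", "winter")
}

#' Capacity-exceedance risk per stratum
#'
#' For each stratum (shift x weekday/weekend, optionally x season) computes
#' the share of shifts whose maximum queue reached or exceeded the
#' threshold: `risk = #(max_queue >= threshold) / n_shifts`, i.e. the
#' probability of at least one half-hour interval at or above 100% bed
#' occupancy during the shift. For integer maxima this equals
#' `1 - F(threshold - 1)` of the stratum ECDF. The comparison is `>=`:
#' 19 patients in 19 beds counts as full occupancy.
#'
#' @param shift_records Output of [max_queue_per_shift()].
#' @param threshold Integer capacity threshold (e.g. bed capacity, 19 at
#'   the reference site); must be `>= 0`.
#' @param by_season Also stratify by season?
#' @return Data.frame with one row per stratum: stratum columns,
#'   `n_shifts`, `risk` (in `[0, 1]`, `NA` for empty strata) and
#'   `threshold`.
#' @export
exceedance_risk <- function(shift_records, threshold, by_season = FALSE) {
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 0L) stop("threshold must be >= 0")
  strata <- list(shift = factor(.shift_levels, levels = .shift_levels),
                 weekend = c(FALSE, TRUE))
  if (by_season) strata$season <- c("summer", "winter")
  grid <- expand.grid(strata, stringsAsFactors = FALSE)
  if (by_season)
    shift_records$season <- season_of(shift_records$operational_day)
  out <- grid
  out$n_shifts <- 0L
  out$risk <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sel <- shift_records$shift == grid$shift[i] &
      shift_records$weekend == grid$weekend[i]
    if (by_season) sel <- sel & shift_records$season == grid$season[i]
    v <- shift_records$max_queue[sel]
    out$n_shifts[i] <- length(v)
    if (length(v)) out$risk[i] <- mean(v >= threshold)
  }
  out$threshold <- threshold
  out
}
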