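# Optional diagnostic plots (ggplot2, Suggests).

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package")
}

#' Time-series plot of arrivals, departures and queue length
#'
#' Per-interval arrivals, departures and the resulting queue for one
#' queue definition, with the capacity line marking 100% bed occupancy.
#'
#' @param intervals Interval table from [aggregate_table()].
#' @param qname Queue name, default `"blackbox"`.
#' @param capacity Optional capacity for a horizontal reference line.
#' @return A ggplot object.
#' @export
plot_queue_series <- function(intervals, qname = "blackbox", capacity = NULL) {
  .need_ggplot()
  df <- data.frame(
    interval_start = rep(intervals$interval_start, 3L),
    value = c(intervals[[paste0("A_", qname)]],
              intervals[[paste0("D_", qname)]],
              intervals[[paste0("Q_", qname)]]),
    series = rep(c("arrivals", "departures", "queue"),
                 each = nrow(intervals)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$interval_start,
                                        y = .data$value,
                                        colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "count per 30-min interval", colour = NULL)
  if (!is.null(capacity))
    p <- p + ggplot2::geom_hline(yintercept = capacity, linetype = "dashed",
                                 colour = "red")
  p
}

#' ECDF plot of per-shift maximum queues
#'
#' One empirical CDF per shift x day-class stratum with a vertical marker
#' at bed capacity; the height of each curve at (capacity - 1) is one minus
#' the stratum's exceedance risk.
#'
#' @param shift_records Output of [max_queue_per_shift()].
#' @param capacity Bed capacity for the vertical marker.
#' @return A ggplot object.
#' @export
plot_max_queue_ecdf <- function(shift_records, capacity = NULL) {
  .need_ggplot()
  df <- shift_records
  df$stratum <- paste(ifelse(df$weekend, "weekend", "weekday"), df$shift)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$max_queue,
                                        colour = .data$stratum)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "max queue per shift", y = "F(x)", colour = NULL)
  if (!is.null(capacity))
    p <- p + ggplot2::geom_vline(xintercept = capacity, linetype = "dotted",
                                 colour = "red")
  p
}
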