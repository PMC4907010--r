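# The non-parametric toolkit used on queue data: Fisher's index of
# dispersion against the Poisson assumption, Spearman rank correlations
# for carry-over effects, and Kruskal-Wallis comparisons of max-queue
# distributions.

#' Fisher's index of dispersion
#'
#' Tests the Poisson assumption on a series of counts. The index is the
#' sample variance over the sample mean (1 under Poisson, > 1 under
#' over-dispersion, as for negative-binomial counts). The statistic
#' `(n-1) * index` is referred to a chi-square distribution with `n-1`
#' degrees of freedom; both tail p-values are reported and the verdict is
#' two-one-sided at `alpha`: `over` when the upper-tail p is below alpha,
#' `under` when the lower-tail p is, otherwise `equi`.
#'
#' @param counts Non-negative integer counts, `n >= 2`, positive mean.
#' @param alpha Significance level for the verdict, default 0.05.
#' @return An `ed_dispersion` list: `index`, `statistic`, `df`,
#'   `p_value` (upper tail, the over-dispersion direction), `p_lower`,
#'   `verdict`, `n`, `mean`, `variance`.
#' @export
fisher_dispersion <- function(counts, alpha = 0.05) {
  counts <- counts[!is.na(counts)]
  n <- length(counts)
  if (n < 2L) stop("need at least 2 counts")
  if (any(counts < 0)) stop("counts must be non-negative")
  m <- mean(counts)
  if (m <= 0) stop("all-zero counts: dispersion index undefined")
  v <- stats::var(counts)
  index <- v / m
  statistic <- (n - 1) * index
  df <- n - 1
  p_upper <- stats::pchisq(statistic, df, lower.tail = FALSE)
  p_lower <- stats::pchisq(statistic, df, lower.tail = TRUE)
  verdict <- if (p_upper < alpha) "over" else if (p_lower < alpha) "under" else "equi"
  structure(list(index = index, statistic = statistic, df = df,
                 p_value = p_upper, p_lower = p_lower, verdict = verdict,
                 n = n, mean = m, variance = v, alpha = alpha),
            class = "ed_dispersion")
}

#' @export
print.ed_dispersion <- function(x, ...) {
  cat(sprintf(
    "Fisher's index of dispersion: %.3f (n = %d, mean = %.2f)\n",
    x$index, x$n, x$mean))
  cat(sprintf("  chi-square = %.1f on %d df; p(over) = %.4g, p(under) = %.4g\n",
              x$statistic, x$df, x$p_value, x$p_lower))
  cat(sprintf("  verdict at alpha = %.2f: %s-dispersed\n", x$alpha, x$verdict))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (mid-rank Pearson). The
#' p-value is two-sided: an exact permutation p for `n <= 10` without ties,
#' otherwise the t-distribution approximation -- both via
#' [stats::cor.test()]. Constant input yields `rho = NA` with a flag rather
#' than an error.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return List `(rho, p_value, n, degenerate)`.
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ct <- suppressWarnings(stats::cor.test(
    x, y, method = "spearman",
    exact = (n <= 10L && !has_ties)))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
       degenerate = FALSE)
}

#' Carry-over correlation between successive shifts or days
#'
#' Tests whether a long maximum queue in one shift predicts a long maximum
#' queue in the following shift (or day). Pairs are formed only with the
#' immediately following partner; a missing partner (gap in the record)
#' drops the pair. Pairings:
#' \describe{
#'   \item{`day_to_evening`}{day shift vs the evening shift of the same
#'     operational day}
#'   \item{`evening_to_night`}{evening vs the night of the same operational
#'     day}
#'   \item{`night_to_day`}{night vs the day shift of the next operational
#'     day}
#'   \item{`day_to_next_day`}{day shift vs the day shift of the next
#'     operational day}
#'   \item{`day_arrivals`}{total arrivals of one operational day vs the
#'     next (requires the `n_arrivals` column)}
#' }
#'
#' @param shift_records Output of [max_queue_per_shift()].
#' @param pairing One of the pairings above.
#' @return An `ed_carry_over` list: `pairing`, `rho`, `p_value`, `n_pairs`.
#' @export
carry_over <- function(shift_records,
                       pairing = c("day_to_evening", "evening_to_night",
                                   "night_to_day", "day_to_next_day",
                                   "day_arrivals")) {
  pairing <- match.arg(pairing)
  sr <- shift_records
  if (pairing == "day_arrivals") {
    if (!"n_arrivals" %in% names(sr))
      stop("pairing 'day_arrivals' needs the n_arrivals column")
    agg <- stats::aggregate(n_arrivals ~ operational_day, sr, sum)
    agg <- agg[order(agg$operational_day), ]
    src <- agg$n_arrivals
    nxt_day <- agg$operational_day + 1L
    tgt <- agg$n_arrivals[match(nxt_day, agg$operational_day)]
    ok <- !is.na(tgt)
    x <- src[ok]; y <- tgt[ok]
  } else {
    spec <- switch(pairing,
      day_to_evening = list(from = "day", to = "evening", lag = 0L),
      evening_to_night = list(from = "evening", to = "night", lag = 0L),
      night_to_day = list(from = "night", to = "day", lag = 1L),
      day_to_next_day = list(from = "day", to = "day", lag = 1L))
    src <- sr[sr$shift == spec$from, c("operational_day", "max_queue")]
    tgt <- sr[sr$shift == spec$to, c("operational_day", "max_queue")]
    m <- match(src$operational_day + spec$lag, tgt$operational_day)
    ok <- !is.na(m)
    x <- src$max_queue[ok]
    y <- tgt$max_queue[m[ok]]
  }
  if (length(x) < 3L) stop("fewer than 3 pairs for pairing '", pairing, "'")
  sp <- spearman_cor(x, y)
  structure(list(pairing = pairing, rho = sp$rho, p_value = sp$p_value,
                 n_pairs = sp$n, degenerate = sp$degenerate),
            class = "ed_carry_over")
}

#' @export
print.ed_carry_over <- function(x, ...) {
  cat(sprintf("Carry-over (%s): rho = %.3f, p = %.4g, n = %d pairs\n",
              x$pairing, x$rho, x$p_value, x$n_pairs))
  invisible(x)
}

#' Kruskal-Wallis comparison of queue-length distributions
#'
#' Tie-corrected Kruskal-Wallis rank sum test (via [stats::kruskal.test()])
#' comparing the distribution of a statistic -- typically per-shift maximum
#' queues -- across two or more groups (shifts, weekday vs weekend, seasons).
#'
#' @param groups Named or unnamed list of `>= 2` non-empty numeric vectors.
#' @return List `(H, df, p_value)`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  if (any(vapply(groups, length, 1L) == 0L)) stop("empty group")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}
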