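#' Percentile bin schemes
#'
#' A bin scheme is an ordered set of half-open percentile intervals
#' `[lo, hi)` within `[0, 100]`; an interval ending at 100 is closed so the
#' top-ranked observation is assignable. `bin_scheme()` builds contiguous
#' intervals from break points; `bin_intervals()` accepts arbitrary
#' (possibly non-contiguous) ranges such as the 1-5, ..., 95-99 percentile
#' bands used for odds-ratio displays.
#'
#' @param breaks increasing numeric break points in `[0, 100]`.
#' @param lo,hi interval bounds, same length.
#' @param labels optional labels (default `"lo-hi"`).
#' @return A `bin_scheme` data frame with `label`, `lo`, `hi`.
#' @export
bin_scheme <- function(breaks = seq(0, 100, by = 5)) {
  stopifnot(length(breaks) >= 2, !is.unsorted(breaks, strictly = TRUE),
            breaks[1] >= 0, breaks[length(breaks)] <= 100)
  k <- length(breaks) - 1
  bin_intervals(breaks[-(k + 1)], breaks[-1])
}

#' @rdname bin_scheme
#' @export
bin_intervals <- function(lo, hi, labels = NULL) {
  stopifnot(length(lo) == length(hi), all(lo < hi),
            all(lo >= 0), all(hi <= 100))
  if (any(utils::head(hi, -1) > utils::tail(lo, -1))) {
    stop("intervals must be non-overlapping and ordered", call. = FALSE)
  }
  if (is.null(labels)) labels <- sprintf("%g-%g", lo, hi)
  structure(data.frame(label = labels, lo = lo, hi = hi,
                       stringsAsFactors = FALSE),
            class = c("bin_scheme", "data.frame"))
}

#' Twenty equal ventiles
#' @return A [bin_scheme()] of 20 five-percentile bins.
#' @export
ventile_scheme <- function() bin_scheme(seq(0, 100, by = 5))

#' Assign scores to percentile bins
#'
#' Percentile rank is `100 * (rank - 1) / n` with average ranks for ties;
#' a score falls in the interval `[lo, hi)` containing its rank (the final
#' interval, if it ends at 100, is closed). Scores outside every interval
#' get `NA`.
#'
#' @param scores numeric vector (no NAs).
#' @param scheme a [bin_scheme()].
#' @return Factor of bin labels with levels in scheme order.
#' @export
assign_bins <- function(scores, scheme = ventile_scheme()) {
  if (length(scores) == 0L) stop("empty score vector", call. = FALSE)
  stopifnot(inherits(scheme, "bin_scheme"), !anyNA(scores))
  pct <- 100 * (rank(scores, ties.method = "average") - 1) / length(scores)
  lab <- rep(NA_character_, length(scores))
  for (i in seq_len(nrow(scheme))) {
    hit <- pct >= scheme$lo[i] &
      (pct < scheme$hi[i] | (scheme$hi[i] >= 100 & pct <= scheme$hi[i]))
    lab[hit] <- scheme$label[i]
  }
  factor(lab, levels = scheme$label)
}

#' Percentile rank of scores
#'
#' Same convention as [assign_bins()]: `100 * (rank - 1) / n`, average
#' ranks for ties. Used for "at or above the Xth percentile" criteria.
#'
#' @param scores numeric vector.
#' @return Percentile ranks in `[0, 100)`.
#' @export
pgs_percentile <- function(scores) {
  100 * (rank(scores, ties.method = "average") - 1) / length(scores)
}

#' Per-bin odds ratio versus the total population
#'
#' The unadjusted OR of the outcome in each bin relative to the whole
#' cohort: `(cases_bin / controls_bin) / (cases_total / controls_total)`.
#' Because bin and total overlap, the confidence interval uses the Woolf
#' log-OR standard error of the bin-versus-complement 2x2 table (a
#' conservative stand-in, tagged in `method`), centred on the reported OR.
#' Zero cells get the Haldane-Anscombe 0.5 correction and are flagged.
#' Bins with fewer observations than `privacy_floor` are suppressed.
#'
#' @param bins factor from [assign_bins()].
#' @param outcome binary outcome aligned with `bins`.
#' @param conf confidence level.
#' @param privacy_floor minimum bin size before suppression.
#' @return Data frame with one row per bin: `bin`, `n`, `n_cases`, `or`,
#'   `lo`, `hi`, `method`, `flag`.
#' @export
bin_or_vs_total <- function(bins, outcome, conf = 0.95, privacy_floor = 5L) {
  y <- as_status01(outcome)
  stopifnot(length(bins) == length(y))
  if (length(unique(y)) < 2L) {
    stop("outcome must include both classes", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  cases_t <- sum(y == 1); ctrls_t <- sum(y == 0)
  res <- lapply(levels(bins), function(b) {
    inb <- !is.na(bins) & bins == b
    n <- sum(inb)
    if (n == 0L) {
      return(data.frame(bin = b, n = 0L, n_cases = 0L, or = NA_real_,
                        lo = NA_real_, hi = NA_real_,
                        method = "woolf-complement", flag = "suppressed"))
    }
    a <- sum(y[inb] == 1); bq <- n - a
    cc <- cases_t - a; dd <- ctrls_t - bq
    if (n < privacy_floor) {
      return(data.frame(bin = b, n = n, n_cases = NA_integer_, or = NA_real_,
                        lo = NA_real_, hi = NA_real_,
                        method = "woolf-complement", flag = "suppressed"))
    }
    flag <- ""
    ac <- a; bc <- bq; ccc <- cc; ddc <- dd
    if (min(a, bq, cc, dd) == 0L) {
      ac <- a + 0.5; bc <- bq + 0.5; ccc <- cc + 0.5; ddc <- dd + 0.5
      flag <- "haldane-anscombe"
    }
    # the point estimate only needs the correction when a bin cell is zero;
    # zero complement cells affect the Woolf SE alone
    or <- if (a > 0L && bq > 0L) {
      (a / bq) / (cases_t / ctrls_t)
    } else {
      (ac / bc) / (cases_t / ctrls_t)
    }
    se <- sqrt(1 / ac + 1 / bc + 1 / ccc + 1 / ddc)
    data.frame(bin = b, n = n, n_cases = a,
               or = or, lo = or * exp(-z * se), hi = or * exp(z * se),
               method = "woolf-complement", flag = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-bin mean or proportion with bootstrap confidence interval
#'
#' Per-bin statistic with a seeded percentile bootstrap (resampling within
#' bin). Missing values are dropped per bin; bins with fewer than two
#' non-missing values get no interval; bins below the privacy floor are
#' suppressed.
#'
#' @param bins factor from [assign_bins()].
#' @param values numeric (for `"mean"`) or binary/logical (for
#'   `"proportion"`) vector aligned with `bins`.
#' @param stat `"mean"` or `"proportion"`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param conf confidence level.
#' @param privacy_floor minimum bin size before suppression.
#' @return Data frame: `bin`, `n`, `stat`, `value`, `lo`, `hi`, `method`.
#' @export
summarize_by_bin <- function(bins, values, stat = c("mean", "proportion"),
                             n_boot = 2000, seed = 1L, conf = 0.95,
                             privacy_floor = 5L) {
  stat <- match.arg(stat)
  stopifnot(length(bins) == length(values))
  if (stat == "proportion") values <- as.numeric(values)
  set.seed(substream_seed(seed, "boot"))
  alpha <- (1 - conf) / 2
  res <- lapply(levels(bins), function(b) {
    v <- values[!is.na(bins) & bins == b]
    v <- v[!is.na(v)]
    n <- length(v)
    if (n < privacy_floor) {
      return(data.frame(bin = b, n = n, stat = stat, value = NA_real_,
                        lo = NA_real_, hi = NA_real_,
                        method = "suppressed", stringsAsFactors = FALSE))
    }
    est <- mean(v)
    if (n < 2L) {
      lo <- hi <- NA_real_
    } else {
      reps <- vapply(seq_len(n_boot), function(i) {
        mean(v[sample.int(n, n, replace = TRUE)])
      }, 0)
      q <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
      lo <- q[1]; hi <- q[2]
    }
    data.frame(bin = b, n = n, stat = stat, value = est, lo = lo, hi = hi,
               method = "percentile-bootstrap", stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Crude incidence rate per 1,000 person-years
#'
#' `1000 * events / person_years` with an exact Poisson confidence
#' interval on the event count.
#'
#' @param events number of incident events.
#' @param followup_days follow-up days of every followed individual.
#' @param conf confidence level.
#' @return List with `events`, `person_years`, `rate`, `ci`.
#' @export
incidence_rate <- function(events, followup_days, conf = 0.95) {
  stopifnot(events >= 0, all(followup_days > 0))
  py <- sum(followup_days) / 365.25
  if (py <= 0) stop("zero person-time", call. = FALSE)
  alpha <- 1 - conf
  lo <- if (events == 0) 0 else stats::qchisq(alpha / 2, 2 * events) / 2
  hi <- stats::qchisq(1 - alpha / 2, 2 * (events + 1)) / 2
  list(events = events, person_years = py,
       rate = 1000 * events / py,
       ci = 1000 * c(lo, hi) / py)
}

#' Plot a per-bin summary table
#'
#' Minimal base-graphics hook for ventile figures: point estimates with
#' interval whiskers by bin.
#'
#' @param x output of [summarize_by_bin()] or [bin_or_vs_total()].
#' @param ylab y-axis label.
#' @param ... passed to [plot()].
#' @export
plot_bins <- function(x, ylab = NULL, ...) {
  val <- if ("value" %in% names(x)) x$value else x$or
  if (is.null(ylab)) ylab <- if ("value" %in% names(x)) "statistic" else "odds ratio"
  k <- seq_len(nrow(x))
  plot(k, val, xlab = "bin", ylab = ylab, xaxt = "n", pch = 19,
       ylim = range(c(x$lo, x$hi, val), na.rm = TRUE), ...)
  graphics::axis(1, at = k, labels = x$bin, las = 2, cex.axis = 0.7)
  graphics::segments(k, x$lo, k, x$hi)
  invisible(x)
}
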