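# Nonparametric rest-activity rhythm indexes. All operate on the valid-day
# hourly matrices produced by hourly_aggregate(), or on the masked minute
# stream for the lagged autocorrelation and peak counts. Undefined metrics
# are returned as NA (with the reason retrievable via attr "reason"), never
# as zeros.

.undefined <- function(reason) structure(NA_real_, reason = reason)

#' Interdaily stability (IS)
#'
#' Ratio of the variance of the average 24-hour profile to the total
#' variance of the hour-aggregated data: with N the number of present
#' cells, `x_bar_h` the clock-hour means, `x_bar` the grand mean and `p`
#' the number of clock hours represented (24 for complete data),
#' `IS = (N * sum_h (x_bar_h - x_bar)^2) / (p * sum_i (x_i - x_bar)^2)`.
#' 1 means perfectly repeated days; values near 0 mean no stable profile.
#'
#' @param hourly Day x 24 matrix of hourly aggregates (NA = missing cell).
#' @return IS in \[0, 1\] (NA with a reason attribute when undefined).
#' @export
interdaily_stability <- function(hourly) {
  x <- as.matrix(hourly)
  n_ok <- sum(!is.na(x))
  if (nrow(x) < 2 || n_ok < 2) return(.undefined("fewer than 2 valid days"))
  grand <- mean(x, na.rm = TRUE)
  tot <- sum((x - grand)^2, na.rm = TRUE)
  if (tot <= 0) return(.undefined("constant series"))
  hmeans <- colMeans(x, na.rm = TRUE)
  hmeans <- hmeans[is.finite(hmeans)]
  (n_ok * sum((hmeans - grand)^2)) / (length(hmeans) * tot)
}

#' Intradaily variability (IV)
#'
#' Normalized mean square of successive hourly differences:
#' `IV = (N * sum (x_i - x_(i-1))^2) / (m * sum (x_i - x_bar)^2)` with N the
#' number of present cells and m the number of successive pairs used
#' (N - 1 for complete data). Differences are taken only between
#' time-adjacent present hours - within a day, and across midnight only
#' between consecutive calendar valid days; gaps are never bridged.
#' About 2 for white noise, 4 for strict hourly alternation.
#'
#' @param hourly Day x 24 matrix with row names the ISO dates of the days.
#' @return IV >= 0 (NA with a reason when undefined).
#' @export
intradaily_variability <- function(hourly) {
  x <- as.matrix(hourly)
  v <- .flatten_hourly(x)
  ok <- !is.na(v$value)
  n_ok <- sum(ok)
  if (n_ok < 2) return(.undefined("fewer than 2 valid hours"))
  grand <- mean(v$value[ok])
  tot <- sum((v$value[ok] - grand)^2)
  if (tot <= 0) return(.undefined("constant series"))
  adj <- which(ok[-1] & ok[-length(ok)] & diff(v$slot) == 1)
  if (length(adj) < 1) return(.undefined("no adjacent hour pairs"))
  d2 <- (v$value[adj + 1] - v$value[adj])^2
  (n_ok * sum(d2)) / (length(adj) * tot)
}

# flatten a day x 24 matrix in time order; slot is an absolute hour index so
# that consecutive slots differ by 1 exactly when the hours are adjacent in
# real time (midnight adjacency requires consecutive calendar dates)
.flatten_hourly <- function(x) {
  dates <- as.Date(rownames(x))
  if (is.null(dates) || anyNA(dates)) dates <- as.Date("2000-01-01") + 2 * seq_len(nrow(x))
  slot <- rep(as.numeric(dates) * 24, each = 24) + rep(0:23, nrow(x))
  list(value = as.vector(t(x)), slot = slot)
}

#' M10, L5 and relative amplitude from a mean 24-hour profile
#'
#' M10 is the maximum over the 24 circular start hours of the mean of 10
#' consecutive hourly values of the average-day profile; L5 the minimum over
#' 5-hour circular windows; `RA = (M10 - L5) / (M10 + L5)`. Window midpoints
#' are reported as clock hours (window center).
#'
#' @param profile Numeric 24-vector (hour 0-23 means) or the data.frame from
#'   [mean_24h_profile()].
#' @return list with `m10`, `l5`, `ra`, `m10_midpoint`, `l5_midpoint`.
#' @export
m10_l5_ra <- function(profile) {
  if (is.data.frame(profile)) profile <- profile$mean
  stopifnot(length(profile) == 24)
  if (anyNA(profile)) {
    na <- .undefined("profile has missing hours")
    return(list(m10 = na, l5 = na, ra = na,
                m10_midpoint = na, l5_midpoint = na))
  }
  win_means <- function(len) {
    ext <- c(profile, profile)
    vapply(0:23, function(s) mean(ext[s + seq_len(len)]), numeric(1))
  }
  w10 <- win_means(10)
  w5 <- win_means(5)
  s10 <- which.max(w10) - 1L
  s5 <- which.min(w5) - 1L
  m10 <- w10[s10 + 1L]
  l5 <- w5[s5 + 1L]
  ra <- if ((m10 + l5) > 0) (m10 - l5) / (m10 + l5) else
    .undefined("M10 + L5 is zero")
  list(m10 = m10, l5 = l5, ra = ra,
       m10_midpoint = .mod24(s10 + 5), l5_midpoint = .mod24(s5 + 2.5))
}

#' Intradaily coefficient of variation (ICV)
#'
#' For each clock hour h with across-day mean m_h > 0 and at least 2 present
#' days, `CV_h = SD_h / m_h` (sample SD across days); ICV is the mean of the
#' eligible CV_h. Higher values indicate a less stable within-day pattern.
#' The alternate within-hour reading (CV of minute values inside each hourly
#' cell, averaged) is available through [extract_biomarkers()]'s
#' `icv_mode = "within_hour"`.
#'
#' @param hourly Day x 24 matrix of hourly aggregates.
#' @return ICV >= 0 (NA with a reason when undefined).
#' @export
intradaily_cv <- function(hourly) {
  x <- as.matrix(hourly)
  if (nrow(x) < 2) return(.undefined("fewer than 2 valid days"))
  cvs <- apply(x, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    m <- mean(v)
    if (m <= 0) return(NA_real_)
    stats::sd(v) / m
  })
  cvs <- cvs[is.finite(cvs)]
  if (length(cvs) == 0) return(.undefined("no eligible hour"))
  mean(cvs)
}

# within-hour CV matrix: CV of valid minute values inside each eligible
# hourly cell of the valid days (>= hour_min_minutes valid minutes, mean > 0)
.within_hour_cv <- function(series, day_set, stream = "steps") {
  values <- if (stream == "steps") series$steps else series$heart_rate
  .within_hour_cv_values(series, day_set, values)
}

.within_hour_cv_values <- function(series, day_set, values) {
  valid_dates <- day_set$days$date[day_set$days$valid]
  n_days <- length(valid_dates)
  min_min <- if (is.null(day_set$hour_min_minutes)) 30 else
    day_set$hour_min_minutes
  out <- matrix(NA_real_, n_days, 24,
                dimnames = list(as.character(valid_dates), 0:23))
  day <- .date_of(series$time)
  hour <- .hour_of(series$time)
  keep <- series$valid & day %in% valid_dates
  if (!any(keep)) return(out)
  f <- interaction(match(day[keep], valid_dates), hour[keep], drop = TRUE)
  stats_by <- tapply(values[keep], f, function(v) {
    if (length(v) < min_min) return(NA_real_)
    m <- mean(v)
    if (m <= 0) return(NA_real_)
    stats::sd(v) / m
  })
  key <- strsplit(names(stats_by), ".", fixed = TRUE)
  di <- vapply(key, function(k) as.integer(k[1]), integer(1))
  hi <- vapply(key, function(k) as.integer(k[2]), integer(1))
  out[cbind(di, hi + 1L)] <- as.numeric(stats_by)
  out
}

#' Day-lagged autocorrelation of a binned minute stream
#'
#' Bins the masked minute stream into `bin_minutes`-minute means and returns
#' the Pearson correlation between the binned series and itself shifted by
#' exactly 24 hours (1440 / `bin_minutes` bins), over index pairs where both
#' values are present.
#'
#' @param values Minute-level stream (NA = missing), in time order, gap-free.
#' @param bin_minutes Bin width: 15, 30 or 60 minutes.
#' @return Correlation in \[-1, 1\] (NA with a reason when undefined).
#' @export
day_lag_autocorrelation <- function(values, bin_minutes = c(60, 30, 15)) {
  bin_minutes <- bin_minutes[1]
  stopifnot(bin_minutes %in% c(15, 30, 60))
  n_bins <- length(values) %/% bin_minutes
  if (n_bins < 2 * 1440 / bin_minutes) {
    return(.undefined("fewer than 2 days after binning"))
  }
  v <- values[seq_len(n_bins * bin_minutes)]
  m <- matrix(v, nrow = bin_minutes)
  binned <- colMeans(m, na.rm = TRUE)
  binned[colSums(!is.na(m)) == 0] <- NA_real_
  lag <- 1440 %/% bin_minutes
  a <- binned[seq_len(n_bins - lag)]
  b <- binned[seq_len(n_bins - lag) + lag]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) return(.undefined("fewer than 3 overlapping pairs"))
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    return(.undefined("constant series"))
  }
  stats::cor(a[ok], b[ok])
}

#' Robust z-score peak counts
#'
#' Smoothed z-score peak detector over the masked minute stream: a running
#' mean and SD of the last `lag` filtered samples flag a sample as signal
#' when `x - mean > threshold * SD`; flagged samples update the filtered
#' series as `influence * x + (1 - influence) * previous filtered value`.
#' A peak is a maximal run of consecutive positive-signal samples, assigned
#' to the day it starts on. Missing samples are skipped without resetting
#' the detector state. Returns the mean and sample SD of daily peak counts
#' over days contributing at least `lag` samples; all-missing days
#' contribute nothing (not zero).
#'
#' @param values Minute-level stream (NA = missing), in time order.
#' @param dates Day label per sample (same length as `values`).
#' @param lag Detector window length in samples (default 60).
#' @param threshold Signal threshold in robust z units (default 3).
#' @param influence Weight of flagged samples in the filtered series
#'   (default 0.1).
#' @return list with `peaks_mean`, `peaks_sd`, and `daily_counts`.
#' @export
robust_peak_counts <- function(values, dates, lag = 60, threshold = 3,
                               influence = 0.1) {
  stopifnot(length(values) == length(dates), lag >= 2)
  ok <- !is.na(values)
  x <- values[ok]
  day <- as.character(dates[ok])
  n <- length(x)
  if (n <= lag) {
    na <- .undefined("fewer samples than detector lag")
    return(list(peaks_mean = na, peaks_sd = na,
                daily_counts = integer(0)))
  }
  signal <- integer(n)
  filtered <- x
  # running sums over the trailing window of filtered values
  wsum <- sum(filtered[1:lag])
  wsq <- sum(filtered[1:lag]^2)
  for (i in (lag + 1):n) {
    mu <- wsum / lag
    varw <- max(0, wsq / lag - mu^2)
    s <- sqrt(varw)
    if ((x[i] - mu) > threshold * s && s > 0) {
      signal[i] <- 1L
      filtered[i] <- influence * x[i] + (1 - influence) * filtered[i - 1]
    } else {
      signal[i] <- 0L
      filtered[i] <- x[i]
    }
    old <- filtered[i - lag]
    wsum <- wsum + filtered[i] - old
    wsq <- wsq + filtered[i]^2 - old^2
  }
  starts <- which(signal == 1L & c(0L, signal[-n]) == 0L)
  peak_day <- day[starts]
  days_counted <- names(which(table(day) >= lag))
  counts <- vapply(days_counted, function(d) sum(peak_day == d), integer(1))
  list(peaks_mean = mean(counts),
       peaks_sd = .sample_sd(counts),
       daily_counts = counts)
}
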