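# Heart-rate biomarker family. All metrics are computed over the valid
# minutes of valid days only (the series is masked through the day set).

#' Resting heart rate from zero-step 15-minute blocks
#'
#' Partitions each valid day into contiguous 15-minute blocks aligned to
#' :00/:15/:30/:45. A block qualifies iff all 15 minutes are valid and every
#' step value is 0; RHR is the mean heart rate over all minutes of all
#' qualifying blocks.
#'
#' @param series A [participant_series()].
#' @param day_set The participant's `valid_day_set`.
#' @param require_complete Require all 15 minutes of a block to be valid
#'   (default TRUE; when FALSE a block qualifies if every *present* minute
#'   has 0 steps and at least 10 minutes are present).
#' @return list with `rhr` (bpm), `rhr_sd`, `n_blocks`.
#' @export
resting_heart_rate <- function(series, day_set, require_complete = TRUE) {
  masked <- .mask_invalid_days(series, day_set)
  block <- floor(as.numeric(masked$time) / (15 * 60))
  valid <- masked$valid
  zero <- valid & masked$steps == 0
  n_valid <- tapply(valid, block, sum)
  n_zero <- tapply(zero, block, sum)
  qualifies <- if (require_complete) {
    n_valid == 15 & n_zero == 15
  } else {
    n_valid >= 10 & n_zero == n_valid
  }
  qblocks <- as.numeric(names(qualifies))[qualifies]
  use <- valid & block %in% qblocks
  if (!any(use)) {
    na <- .undefined("no qualifying rest block")
    return(list(rhr = na, rhr_sd = na, n_blocks = 0L))
  }
  list(rhr = mean(masked$heart_rate[use]),
       rhr_sd = .sample_sd(masked$heart_rate[use]),
       n_blocks = length(qblocks))
}

#' Delta resting heart rate
#'
#' `dRHR = overall mean heart rate - RHR`; small values indicate a blunted
#' contrast between activity and rest. Missingness propagates.
#'
#' @param hr_mean Overall mean heart rate (bpm).
#' @param rhr Resting heart rate (bpm).
#' @return dRHR in bpm.
#' @export
delta_rhr <- function(hr_mean, rhr) {
  if (is.na(hr_mean) || is.na(rhr)) return(NA_real_)
  hr_mean - rhr
}

#' Daytime and nighttime heart rate
#'
#' Daytime heart rate is the mean over valid minutes in \[14:00, 16:00) of
#' valid days; each of the three night windows (\[0,2), \[2,4), \[4,6)) is
#' averaged likewise, and the nighttime heart rate is the unweighted mean of
#' the three window means (missing if any window is empty).
#'
#' @param series A [participant_series()].
#' @param day_set The participant's `valid_day_set`.
#' @return list with `day_hr`, `night_hr`, `night_hr_windows` (length 3).
#' @export
day_night_hr <- function(series, day_set) {
  masked <- .mask_invalid_days(series, day_set)
  h <- .clock_hour(series$time)
  win_mean <- function(lo, hi) {
    use <- masked$valid & h >= lo & h < hi
    if (!any(use)) return(NA_real_)
    mean(masked$heart_rate[use])
  }
  day_hr <- win_mean(14, 16)
  wins <- c(win_mean(0, 2), win_mean(2, 4), win_mean(4, 6))
  night_hr <- if (anyNA(wins)) .undefined("empty night window") else mean(wins)
  if (is.na(day_hr)) day_hr <- .undefined("empty day window")
  list(day_hr = day_hr, night_hr = night_hr, night_hr_windows = wins)
}

#' Root mean square of successive differences (RMSSD)
#'
#' `sqrt(mean((x[i+1] - x[i])^2))` over consecutive pairs where both values
#' are present; pairs spanning a gap are excluded.
#'
#' @param values Ordered sequence (bpm samples; NA = missing).
#' @return RMSSD in the units of `values` (NA if no usable pair).
#' @export
rmssd <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 2) return(.undefined("fewer than 2 values"))
  a <- x[-length(x)]
  b <- x[-1]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(.undefined("no consecutive present pair"))
  sqrt(mean((b[ok] - a[ok])^2))
}

#' Full heart-rate biomarker record
#'
#' Computes the heart-rate family for one participant: overall mean/SD/CV
#' over valid minutes of valid days, RHR ([resting_heart_rate()]), dRHR,
#' day/night heart rate ([day_night_hr()]), and RMSSD on the raw minute
#' stream and on the hourly means (adjacent clock hours within the same day
#' only).
#'
#' @param series A [participant_series()].
#' @param day_set The participant's `valid_day_set` with hourly matrices.
#' @return Named list of metrics (see column names of
#'   [extract_biomarkers()]).
#' @export
heart_rate_metrics <- function(series, day_set) {
  masked <- .mask_invalid_days(series, day_set)
  hr <- masked$heart_rate[masked$valid]
  hr_mean <- if (length(hr)) mean(hr) else .undefined("no valid minutes")
  hr_sd <- .sample_sd(masked$heart_rate[masked$valid])
  hr_cv <- if (!is.na(hr_mean) && hr_mean > 0 && !is.na(hr_sd)) {
    hr_sd / hr_mean
  } else NA_real_
  rest <- resting_heart_rate(series, day_set)
  dn <- day_night_hr(series, day_set)
  hh <- .hourly_matrix(day_set, "heart_rate")
  # hourly RMSSD: adjacent clock hours within the same day only
  hourly_pairs_rmssd <- if (nrow(hh) == 0) .undefined("no valid days") else {
    d2 <- (hh[, -1, drop = FALSE] - hh[, -24, drop = FALSE])^2
    d2 <- d2[!is.na(d2)]
    if (length(d2) == 0) .undefined("no adjacent hour pair") else
      sqrt(mean(d2))
  }
  list(hr_mean = hr_mean, hr_sd = hr_sd, hr_cv = hr_cv,
       rhr = rest$rhr, rhr_sd = rest$rhr_sd,
       d_rhr = delta_rhr(hr_mean, rest$rhr),
       day_hr = dn$day_hr, night_hr = dn$night_hr,
       night_hr_windows = dn$night_hr_windows,
       rmssd_raw = rmssd(masked$heart_rate),
       rmssd_hourly = hourly_pairs_rmssd)
}
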