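#' Extract the digital-biomarker feature vector for one participant
#'
#' Runs preprocessing and the selected metric families on one participant
#' series and returns a one-row data.frame. Step-based and heart-rate-based
#' rhythm metrics share code and carry `.st` / `.hr` suffixes. The extended
#' cosinor is fitted on minute-level heart rate and (to tame zero-inflation)
#' on hourly step aggregates; `cosinor_steps_resolution = "minute"` switches
#' the step fit to minute level.
#'
#' Columns: `Steps` (mean daily step total over valid days), nonparametric
#' family `IS, IV, M10, L5, RA, ICV, AC.60m, AC.30m, AC.15m, Peaks.mean,
#' Peaks.sd` with `.st`/`.hr` suffixes; cosinor family `Minimum, Amplitude,
#' alpha, beta, Acrotime, F_pseudo, UpMesor, DownMesor, MESOR` with
#' suffixes; heart-rate family `HR.mean, HR.sd, HR.cv, RHR, dRHR, DHR, NHR,
#' NHR.w1..w3, RMSSD.raw, RMSSD.hourly`; plus `participant_id`, `included`,
#' `n_valid_days`.
#'
#' @param series A [participant_series()].
#' @param families Metric families to compute (subset of
#'   `"nonparametric"`, `"cosinor"`, `"hr"`).
#' @param icv_mode `"across_days"` (clock-hour CV across days, default) or
#'   `"within_hour"` (CV of minute values within each hourly cell,
#'   averaged).
#' @param cosinor_steps_resolution `"hourly"` (default) or `"minute"`.
#' @param peak_lag,peak_threshold,peak_influence Robust peak-detector
#'   parameters (see [robust_peak_counts()]).
#' @param valid_day_hours,min_valid_days,hour_min_minutes,rescale_partial
#'   Preprocessing rules (see [compute_valid_days()] and
#'   [hourly_aggregate()]).
#' @return One-row data.frame. Metrics are NA when the participant is not
#'   included or a metric is undefined.
#' @export
extract_biomarkers <- function(series,
                               families = c("nonparametric", "cosinor", "hr"),
                               icv_mode = c("across_days", "within_hour"),
                               cosinor_steps_resolution = c("hourly", "minute"),
                               peak_lag = 60, peak_threshold = 3,
                               peak_influence = 0.1,
                               valid_day_hours = 20, min_valid_days = 5,
                               hour_min_minutes = 30, rescale_partial = TRUE) {
  families <- match.arg(families, several.ok = TRUE)
  icv_mode <- match.arg(icv_mode)
  cosinor_steps_resolution <- match.arg(cosinor_steps_resolution)
  ds <- compute_valid_days(series, valid_day_hours, min_valid_days)
  ds <- hourly_aggregate(series, ds, hour_min_minutes, rescale_partial)
  out <- list(participant_id = series$participant_id,
              included = ds$included,
              n_valid_days = sum(ds$days$valid))
  masked <- .mask_invalid_days(series, ds)
  dates <- .date_of(series$time)

  # mean daily step total over valid days (raw valid-minute sums)
  valid_dates <- ds$days$date[ds$days$valid]
  out$Steps <- if (length(valid_dates) && ds$included) {
    daily <- tapply(masked$steps[masked$valid], dates[masked$valid], sum)
    mean(daily[as.character(valid_dates)], na.rm = TRUE)
  } else NA_real_

  if (!ds$included) {
    return(.pad_feature_row(out, families))
  }

  if ("nonparametric" %in% families) {
    for (stream in c("st", "hr")) {
      hm <- if (stream == "st") ds$hourly_steps else ds$hourly_hr
      vals <- if (stream == "st") masked$steps else masked$heart_rate
      profile <- mean_24h_profile(ds, if (stream == "st") "steps" else
        "heart_rate")
      ml <- m10_l5_ra(profile$mean)
      icv <- if (icv_mode == "across_days") intradaily_cv(hm) else {
        cvm <- .within_hour_cv(series, ds,
                               if (stream == "st") "steps" else "heart_rate")
        cvs <- cvm[!is.na(cvm)]
        if (length(cvs)) mean(cvs) else NA_real_
      }
      pk <- robust_peak_counts(vals, dates, lag = peak_lag,
                               threshold = peak_threshold,
                               influence = peak_influence)
      vals_named <- list(
        IS = as.numeric(interdaily_stability(hm)),
        IV = as.numeric(intradaily_variability(hm)),
        M10 = as.numeric(ml$m10), L5 = as.numeric(ml$l5),
        RA = as.numeric(ml$ra), ICV = as.numeric(icv),
        AC.60m = as.numeric(day_lag_autocorrelation(vals, 60)),
        AC.30m = as.numeric(day_lag_autocorrelation(vals, 30)),
        AC.15m = as.numeric(day_lag_autocorrelation(vals, 15)),
        Peaks.mean = as.numeric(pk$peaks_mean),
        Peaks.sd = as.numeric(pk$peaks_sd))
      names(vals_named) <- .suffix(names(vals_named), stream)
      out <- c(out, vals_named)
    }
  }

  if ("cosinor" %in% families) {
    t_min <- .clock_hour(series$time)
    fit_hr <- fit_extended_cosinor(t_min, masked$heart_rate)
    out <- c(out, .cosinor_row(fit_hr, "hr"))
    if (cosinor_steps_resolution == "hourly") {
      flat <- .flatten_hourly(ds$hourly_steps)
      t_st <- rep(0:23 + 0.5, nrow(ds$hourly_steps))
      fit_st <- fit_extended_cosinor(t_st, flat$value)
    } else {
      fit_st <- fit_extended_cosinor(t_min, masked$steps)
    }
    out <- c(out, .cosinor_row(fit_st, "st"))
  }

  if ("hr" %in% families) {
    hm <- heart_rate_metrics(series, ds)
    out <- c(out, list(
      HR.mean = as.numeric(hm$hr_mean), HR.sd = as.numeric(hm$hr_sd),
      HR.cv = as.numeric(hm$hr_cv), RHR = as.numeric(hm$rhr),
      dRHR = as.numeric(hm$d_rhr), DHR = as.numeric(hm$day_hr),
      NHR = as.numeric(hm$night_hr),
      NHR.w1 = hm$night_hr_windows[1], NHR.w2 = hm$night_hr_windows[2],
      NHR.w3 = hm$night_hr_windows[3],
      RMSSD.raw = as.numeric(hm$rmssd_raw),
      RMSSD.hourly = as.numeric(hm$rmssd_hourly)))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

.suffix <- function(nm, stream) {
  # AC.st.60m style for autocorrelation, Peaks.st.mean for peaks, X.st else
  vapply(nm, function(x) {
    parts <- strsplit(x, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2) paste(parts[1], stream, parts[2], sep = ".")
    else paste(x, stream, sep = ".")
  }, character(1), USE.NAMES = FALSE)
}

.cosinor_row <- function(fit, stream) {
  vals <- list(Minimum = fit$minimum, Amplitude = fit$amplitude,
               alpha = fit$alpha, beta = fit$beta,
               Acrotime = fit$acrotime, F_pseudo = fit$f_pseudo,
               UpMesor = fit$up_mesor, DownMesor = fit$down_mesor,
               MESOR = fit$mesor)
  names(vals) <- paste(names(vals), stream, sep = ".")
  vals
}

.FEATURE_COLUMNS <- local({
  np <- c("IS", "IV", "M10", "L5", "RA", "ICV",
          "AC.60m", "AC.30m", "AC.15m", "Peaks.mean", "Peaks.sd")
  cs <- c("Minimum", "Amplitude", "alpha", "beta", "Acrotime", "F_pseudo",
          "UpMesor", "DownMesor", "MESOR")
  hrm <- c("HR.mean", "HR.sd", "HR.cv", "RHR", "dRHR", "DHR", "NHR",
           "NHR.w1", "NHR.w2", "NHR.w3", "RMSSD.raw", "RMSSD.hourly")
  list(nonparametric = c(.suffix(np, "st"), .suffix(np, "hr")),
       cosinor = c(paste(cs, "hr", sep = "."), paste(cs, "st", sep = ".")),
       hr = hrm)
})

.pad_feature_row <- function(out, families) {
  for (fam in families) {
    for (col in .FEATURE_COLUMNS[[fam]]) out[[col]] <- NA_real_
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Extract biomarkers for a whole cohort
#'
#' Applies [extract_biomarkers()] to each series; returns a wide feature
#' table, one row per participant (excluded participants keep their row
#' with `included = FALSE` and NA metrics; [build_feature_table()] drops
#' them).
#'
#' @param series_list Named list of `participant_series`.
#' @param ... Passed to [extract_biomarkers()].
#' @return data.frame with one row per participant.
#' @export
extract_cohort_features <- function(series_list, ...) {
  rows <- lapply(series_list, extract_biomarkers, ...)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
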