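#' Apply the valid-day and inclusion rules to a participant series
#'
#' A calendar day (local midnight boundary) is valid when it holds at least
#' `valid_day_hours` hours of concurrent step and heart-rate data; a
#' participant is included when at least `min_valid_days` days are valid.
#' Valid-hour totals are (valid minutes)/60.
#'
#' @param series A [participant_series()].
#' @param valid_day_hours Hours of concurrent data required per day
#'   (default 20).
#' @param min_valid_days Valid days required for inclusion (default 5).
#' @return A `valid_day_set`: list with `participant_id`, `days` (data.frame
#'   of `date`, `valid_minutes`, `valid_hours`, `valid`), `included`, the
#'   rule parameters, and (after [hourly_aggregate()]) hourly matrices.
#' @export
compute_valid_days <- function(series, valid_day_hours = 20,
                               min_valid_days = 5) {
  stopifnot(inherits(series, "participant_series"))
  day <- .date_of(series$time)
  vm <- tapply(series$valid, day, sum)
  days <- data.frame(date = as.Date(names(vm)),
                     valid_minutes = as.integer(vm),
                     row.names = NULL)
  days$valid_hours <- days$valid_minutes / 60
  days$valid <- days$valid_hours >= valid_day_hours
  structure(
    list(participant_id = series$participant_id,
         days = days,
         included = sum(days$valid) >= min_valid_days,
         valid_day_hours = valid_day_hours,
         min_valid_days = min_valid_days,
         hourly_steps = NULL,
         hourly_hr = NULL),
    class = "valid_day_set")
}

#' @export
print.valid_day_set <- function(x, ...) {
  cat("<valid_day_set> ", x$participant_id, "\n", sep = "")
  cat("  ", sum(x$days$valid), " of ", nrow(x$days), " days valid (>= ",
      x$valid_day_hours, " h); included = ", x$included, "\n", sep = "")
  invisible(x)
}

#' Hourly aggregates over valid days
#'
#' Fills the `hourly_steps` and `hourly_hr` matrices (valid days x 24 clock
#' hours) of a `valid_day_set`. A cell is present only when the clock hour
#' holds at least `hour_min_minutes` valid minutes. Hourly steps are the sum
#' of valid-minute steps, rescaled to a full hour by 60/(valid minutes) when
#' `rescale_partial = TRUE` (default) so partially worn hours are not
#' systematically underestimated; hourly heart rate is the mean of
#' valid-minute values.
#'
#' @param series The [participant_series()] the day set came from.
#' @param day_set A `valid_day_set` for the same participant.
#' @param hour_min_minutes Minimum valid minutes per hourly cell (default 30).
#' @param rescale_partial Rescale partial-hour step sums to a full hour.
#' @return The `valid_day_set` with hourly matrices filled (row names are the
#'   valid dates).
#' @export
hourly_aggregate <- function(series, day_set, hour_min_minutes = 30,
                             rescale_partial = TRUE) {
  stopifnot(inherits(series, "participant_series"),
            inherits(day_set, "valid_day_set"),
            identical(series$participant_id, day_set$participant_id))
  valid_dates <- day_set$days$date[day_set$days$valid]
  n_days <- length(valid_dates)
  hs <- matrix(NA_real_, n_days, 24,
               dimnames = list(as.character(valid_dates), 0:23))
  hh <- hs
  if (n_days > 0) {
    day <- .date_of(series$time)
    hour <- .hour_of(series$time)
    keep <- series$valid & day %in% valid_dates
    if (any(keep)) {
      di <- match(day[keep], valid_dates)
      hi <- hour[keep] + 1L
      cell <- (di - 1L) * 24L + hi
      nmin <- tabulate(cell, nbins = n_days * 24L)
      ssum <- rowsum(series$steps[keep], cell)
      hsum <- rowsum(series$heart_rate[keep], cell)
      idx <- as.integer(rownames(ssum))
      ok <- nmin[idx] >= hour_min_minutes
      scale <- if (rescale_partial) 60 / nmin[idx] else rep(1, length(idx))
      hs_flat <- rep(NA_real_, n_days * 24L)
      hh_flat <- hs_flat
      hs_flat[idx[ok]] <- ssum[ok, 1] * scale[ok]
      hh_flat[idx[ok]] <- hsum[ok, 1] / nmin[idx][ok]
      hs <- matrix(hs_flat, n_days, 24, byrow = TRUE,
                   dimnames = dimnames(hs))
      hh <- matrix(hh_flat, n_days, 24, byrow = TRUE,
                   dimnames = dimnames(hh))
    }
  }
  day_set$hourly_steps <- hs
  day_set$hourly_hr <- hh
  day_set$hour_min_minutes <- hour_min_minutes
  day_set$rescale_partial <- rescale_partial
  day_set
}

#' Mean 24-hour profile across valid days
#'
#' Per clock hour, the mean and sample SD across valid days of the hourly
#' aggregate; hours with no present cells are missing.
#'
#' @param day_set A `valid_day_set` with hourly matrices
#'   (see [hourly_aggregate()]).
#' @param stream `"steps"` or `"heart_rate"`.
#' @return data.frame with columns `hour` (0-23), `mean`, `sd`, `n_days`.
#' @export
mean_24h_profile <- function(day_set, stream = c("steps", "heart_rate")) {
  stream <- match.arg(stream)
  m <- .hourly_matrix(day_set, stream)
  data.frame(
    hour = 0:23,
    mean = apply(m, 2, function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }),
    sd = apply(m, 2, .sample_sd),
    n_days = colSums(!is.na(m)),
    row.names = NULL)
}

.hourly_matrix <- function(day_set, stream) {
  m <- if (stream == "steps") day_set$hourly_steps else day_set$hourly_hr
  if (is.null(m)) {
    stop("hourly aggregates not computed; call hourly_aggregate() first")
  }
  m
}

# restrict a series to its valid days: invalid-day minutes are masked
.mask_invalid_days <- function(series, day_set) {
  valid_dates <- day_set$days$date[day_set$days$valid]
  keep <- .date_of(series$time) %in% valid_dates & series$valid
  list(time = series$time,
       steps = ifelse(keep, series$steps, NA_real_),
       heart_rate = ifelse(keep, series$heart_rate, NA_real_),
       valid = keep)
}
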