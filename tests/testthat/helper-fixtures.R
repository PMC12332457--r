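# Fixture builders and independent brute-force oracles used across tests.

# dense minute series over full days; steps/hr given as functions of the
# decimal clock hour (recycled per day) or as full-length vectors
make_series <- function(days = 7, steps = function(h) 100,
                        hr = function(h) 70, id = "FX1",
                        start = as.Date("2024-03-04")) {
  n <- days * 1440
  time <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC") + 60 * (0:(n - 1))
  h <- ((0:(n - 1)) %% 1440) / 60
  st <- if (is.function(steps)) steps(h) else steps
  hh <- if (is.function(hr)) hr(h) else hr
  participant_series(id, time, rep_len(st, n), rep_len(hh, n))
}

clock_hours <- function(series) {
  as.numeric(format(series$time, "%H", tz = "UTC")) +
    as.numeric(format(series$time, "%M", tz = "UTC")) / 60
}

hourly_from_series <- function(series, ...) {
  ds <- compute_valid_days(series)
  hourly_aggregate(series, ds, ...)
}

# ---- brute-force oracles (straight double-loop transcriptions) ----

oracle_is <- function(m) {
  vals <- c()
  hsum <- numeric(24); hn <- numeric(24)
  for (d in seq_len(nrow(m))) for (h in 1:24) {
    v <- m[d, h]
    if (!is.na(v)) {
      vals <- c(vals, v)
      hsum[h] <- hsum[h] + v
      hn[h] <- hn[h] + 1
    }
  }
  grand <- mean(vals)
  num <- 0; p <- 0
  for (h in 1:24) if (hn[h] > 0) {
    num <- num + (hsum[h] / hn[h] - grand)^2
    p <- p + 1
  }
  den <- 0
  for (v in vals) den <- den + (v - grand)^2
  length(vals) * num / (p * den)
}

oracle_iv <- function(m) {
  dates <- as.Date(rownames(m))
  vals <- c(); slots <- c()
  for (d in seq_len(nrow(m))) for (h in 1:24) {
    if (!is.na(m[d, h])) {
      vals <- c(vals, m[d, h])
      slots <- c(slots, as.numeric(dates[d]) * 24 + h - 1)
    }
  }
  grand <- mean(vals)
  den <- sum((vals - grand)^2)
  num <- 0; npair <- 0
  for (k in 2:length(vals)) {
    if (slots[k] - slots[k - 1] == 1) {
      num <- num + (vals[k] - vals[k - 1])^2
      npair <- npair + 1
    }
  }
  length(vals) * num / (npair * den)
}

oracle_icv <- function(m) {
  cvs <- c()
  for (h in 1:24) {
    v <- m[, h]
    v <- v[!is.na(v)]
    if (length(v) >= 2 && mean(v) > 0) cvs <- c(cvs, sd(v) / mean(v))
  }
  mean(cvs)
}

oracle_m10_l5 <- function(profile) {
  best10 <- -Inf; best5 <- Inf
  for (s in 0:23) {
    idx10 <- ((s + 0:9) %% 24) + 1
    idx5 <- ((s + 0:4) %% 24) + 1
    best10 <- max(best10, mean(profile[idx10]))
    best5 <- min(best5, mean(profile[idx5]))
  }
  c(m10 = best10, l5 = best5)
}

oracle_daylag_cor <- function(values, bin) {
  n_bins <- length(values) %/% bin
  binned <- rep(NA_real_, n_bins)
  for (k in seq_len(n_bins)) {
    chunk <- values[((k - 1) * bin + 1):(k * bin)]
    if (any(!is.na(chunk))) binned[k] <- mean(chunk, na.rm = TRUE)
  }
  lag <- 1440 / bin
  xs <- c(); ys <- c()
  for (k in seq_len(n_bins - lag)) {
    if (!is.na(binned[k]) && !is.na(binned[k + lag])) {
      xs <- c(xs, binned[k]); ys <- c(ys, binned[k + lag])
    }
  }
  mx <- mean(xs); my <- mean(ys)
  sum((xs - mx) * (ys - my)) /
    sqrt(sum((xs - mx)^2) * sum((ys - my)^2))
}

# random hourly matrix (complete or with missing cells), rownames consecutive
random_hourly <- function(days = 4, missing_frac = 0) {
  m <- matrix(rgamma(days * 24, shape = 2, scale = 50), days, 24)
  if (missing_frac > 0) {
    k <- ceiling(missing_frac * length(m))
    m[sample(length(m), k)] <- NA
  }
  rownames(m) <- as.character(as.Date("2024-03-04") + 0:(days - 1))
  colnames(m) <- 0:23
  m
}
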