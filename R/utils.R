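# Internal helpers shared across modules. Timestamps are naive local time
# carried as POSIXct in the "UTC" zone so that no DST arithmetic ever applies.

.MINUTE <- 60

.as_minute_time <- function(x) {
  t <- as.POSIXct(x, tz = "UTC")
  as.POSIXct(floor(as.numeric(t) / .MINUTE) * .MINUTE,
             origin = "1970-01-01", tz = "UTC")
}

.parse_timestamps <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("T", " ", x, fixed = TRUE)
  # accept "YYYY-MM-DD HH:MM" and "YYYY-MM-DD HH:MM:SS"; NA for malformed
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- as.POSIXct(strptime(x[miss], "%Y-%m-%d %H:%M", tz = "UTC"))
  }
  out
}

.format_timestamp <- function(t) format(t, "%Y-%m-%dT%H:%M", tz = "UTC")

.date_of <- function(t) as.Date(t, tz = "UTC")

.hour_of <- function(t) as.integer(format(t, "%H", tz = "UTC"))

# decimal clock hour (0 <= h < 24) of a minute timestamp
.clock_hour <- function(t) {
  .hour_of(t) + as.integer(format(t, "%M", tz = "UTC")) / 60
}

.mod24 <- function(x) x %% 24

# derive a per-participant RNG seed from a master seed; keeps within 32-bit range
.child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1003 + 7919 * as.numeric(index)) %% 2147483629)
}

.is_missing <- function(x) is.na(x)

.sample_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x)
}
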