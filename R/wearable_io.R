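#' Construct a canonical per-participant minute series
#'
#' Builds a `participant_series` from raw minute samples: timestamps are
#' truncated to whole minutes, the series is expanded to a gap-free minute
#' grid between the first and last observation (absent minutes materialize as
#' missing samples), heart rates of 0 are treated as missing (devices emit
#' gaps, not zeros), and minutes without a heart-rate measurement have their
#' step count forced to missing so that only concurrent-data minutes are
#' usable downstream.
#'
#' @param participant_id Participant identifier (scalar character).
#' @param timestamp Date-times at minute resolution (coerced with
#'   [as.POSIXct()]; naive local time, no time-zone arithmetic).
#' @param steps Non-negative integer step counts (NA allowed).
#' @param heart_rate Heart rate in beats per minute (NA allowed; 0 treated
#'   as missing).
#' @return A `participant_series`: list with elements `participant_id`,
#'   `time` (gap-free POSIXct minute grid), `steps`, `heart_rate`, and
#'   `valid` (`TRUE` iff both streams are present at that minute).
#' @export
participant_series <- function(participant_id, timestamp, steps, heart_rate) {
  stopifnot(length(participant_id) == 1L)
  t <- .as_minute_time(timestamp)
  if (anyNA(t)) stop("unparseable timestamp for participant ", participant_id)
  if (anyDuplicated(t)) {
    dup <- format(t[duplicated(t)][1], "%Y-%m-%d %H:%M")
    stop("duplicate (participant, minute) sample for participant ",
         participant_id, " at ", dup)
  }
  o <- order(t)
  t <- t[o]
  steps <- as.numeric(steps)[o]
  heart_rate <- as.numeric(heart_rate)[o]
  if (any(steps < 0, na.rm = TRUE)) {
    stop("negative step count for participant ", participant_id)
  }
  if (any(!is.finite(heart_rate) & !is.na(heart_rate))) {
    stop("non-finite heart rate for participant ", participant_id)
  }
  heart_rate[!is.na(heart_rate) & heart_rate <= 0] <- NA_real_
  # concurrency rule: steps without heart rate are marked invalid
  steps[is.na(heart_rate)] <- NA_real_

  grid <- seq(t[1], t[length(t)], by = "1 min")
  idx <- match(grid, t)
  steps <- steps[idx]
  heart_rate <- heart_rate[idx]
  structure(
    list(participant_id = as.character(participant_id),
         time = grid,
         steps = steps,
         heart_rate = heart_rate,
         valid = !is.na(steps) & !is.na(heart_rate)),
    class = "participant_series")
}

#' @export
print.participant_series <- function(x, ...) {
  cat("<participant_series> ", x$participant_id, "\n", sep = "")
  cat("  ", length(x$time), " minutes from ",
      format(x$time[1], "%Y-%m-%d %H:%M"), " to ",
      format(x$time[length(x$time)], "%Y-%m-%d %H:%M"), "\n", sep = "")
  cat("  ", sum(x$valid), " valid minutes (",
      sprintf("%.1f", 100 * mean(x$valid)), "%)\n", sep = "")
  invisible(x)
}

#' Read minute-level step and heart-rate streams
#'
#' Reads a raw minute-level table in one of two dialects and returns one
#' canonical [participant_series()] per participant. The `long_csv` dialect
#' has columns `participant_id,timestamp,steps,heart_rate` with ISO-8601
#' minute timestamps. The `fitbit_json` dialect mirrors an intraday-API
#' payload: a top-level `participants` array, each with `participant_id`
#' and a `days` array of `{date, steps: [{time, value}], heart_rate:
#' [{time, value}]}` records. Gzip-compressed files are read transparently.
#'
#' @param path Path to the input file.
#' @param dialect `"long_csv"` (default) or `"fitbit_json"`.
#' @return Named list of `participant_series`.
#' @export
read_minute_table <- function(path, dialect = c("long_csv", "fitbit_json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "long_csv") .read_long_csv(path) else .read_fitbit_json(path)
}

.read_long_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  required <- c("participant_id", "timestamp", "steps", "heart_rate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warning("empty minute table: ", path)
    return(structure(list(), names = character(0)))
  }
  ts <- .parse_timestamps(df$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop("malformed timestamp at row ", bad, ": '", df$timestamp[bad], "'")
  }
  out <- lapply(split(seq_len(nrow(df)), df$participant_id), function(i) {
    participant_series(df$participant_id[i[1]], ts[i],
                       df$steps[i], df$heart_rate[i])
  })
  out[order(names(out))]
}

.read_fitbit_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(payload$participants) || length(payload$participants) == 0) {
    warning("empty minute table: ", path)
    return(structure(list(), names = character(0)))
  }
  out <- lapply(payload$participants, function(p) {
    rows <- lapply(p$days, function(d) {
      st <- .json_stream(d$steps, d$date)
      hr <- .json_stream(d$heart_rate, d$date)
      merged <- merge(st, hr, by = "timestamp", all = TRUE,
                      suffixes = c(".st", ".hr"))
      data.frame(timestamp = merged$timestamp,
                 steps = merged$value.st,
                 heart_rate = merged$value.hr)
    })
    rows <- do.call(rbind, rows)
    participant_series(p$participant_id, rows$timestamp,
                       rows$steps, rows$heart_rate)
  })
  names(out) <- vapply(out, function(s) s$participant_id, character(1))
  out[order(names(out))]
}

.json_stream <- function(entries, date) {
  if (is.null(entries) || length(entries) == 0) {
    return(data.frame(timestamp = character(0), value = numeric(0)))
  }
  data.frame(
    timestamp = paste(date, vapply(entries, `[[`, character(1), "time")),
    value = vapply(entries, function(e) as.numeric(e$value), numeric(1)))
}

#' Write a collection of participant series as long CSV
#'
#' Writes the canonical long-CSV dialect (`participant_id,timestamp,steps,
#' heart_rate`, ISO-8601 minute timestamps, missing values empty). Reading
#' the file back with [read_minute_table()] and writing again is
#' byte-stable.
#'
#' @param series_list Named list of `participant_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_minute_table <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    data.frame(participant_id = s$participant_id,
               timestamp = .format_timestamp(s$time),
               steps = ifelse(is.na(s$steps), "",
                              vapply(s$steps, format, character(1),
                                     trim = TRUE, scientific = FALSE,
                                     digits = 15)),
               heart_rate = ifelse(is.na(s$heart_rate), "",
                                   vapply(s$heart_rate, format, character(1),
                                          trim = TRUE, scientific = FALSE,
                                          digits = 15)))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a questionnaire table
#'
#' Reads the per-participant questionnaire CSV: social frailty index items,
#' demographics, physical and cognitive scores. Expected columns:
#' `participant_id, age, sex, lives_alone, no_daily_conversation,
#' not_feeling_helpful, going_out_less, not_visiting_friends, grip_strength,
#' walking_speed, wlm, tmt_a, tmt_b, dsst`. The five frailty items are 0/1
#' indicators; `wlm` is the word-list-memory total (0-20, immediate
#' recognition plus delayed recall).
#'
#' @param path Path to the CSV file.
#' @return A data.frame of typed questionnaire records.
#' @export
read_questionnaire <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  required <- c("participant_id", "age", "sex", .FRAILTY_ITEMS, "wlm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  for (item in .FRAILTY_ITEMS) {
    v <- df[[item]]
    if (any(!v[!is.na(v)] %in% c(0, 1))) {
      stop("frailty item '", item, "' must be 0/1")
    }
    df[[item]] <- as.integer(v)
  }
  if (any(df$wlm < 0 | df$wlm > 20, na.rm = TRUE)) {
    stop("wlm score outside 0-20")
  }
  df$sex <- factor(df$sex, levels = c("female", "male"))
  df
}

.FRAILTY_ITEMS <- c("lives_alone", "no_daily_conversation",
                    "not_feeling_helpful", "going_out_less",
                    "not_visiting_friends")
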