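# Seeded synthetic cohorts: minute-level step/heart-rate recordings with
# group-dependent ground truth (robust / social prefrailty / social
# frailty), plus matching questionnaire records. Group defaults are
# calibrated to the direction and magnitude of the published cohort means
# (daily steps ~9080/7809/6005, dRHR ordered robust > prefrail > frail,
# fragmentation ordered the other way).

.GROUPS <- c("robust", "prefrail", "frail")

#' Group generating profile
#'
#' Ground-truth parameter set for one frailty group. The heart-rate
#' circadian baseline is an extended-cosinor curve; activity is a two-state
#' (rest/active) minute process whose active probability follows a shifted
#' antilogistic waveform; heart rate couples to the recent step rate and
#' carries AR(1) noise; non-wear appears as random blocks masking both
#' streams.
#'
#' @param group `"robust"`, `"prefrail"` or `"frail"`.
#' @return A `group_profile` list: `cosinor_truth` (minimum, amplitude,
#'   alpha, beta, acrophase for the HR baseline), `daily_steps_target`,
#'   `activity_intensity` (steps/min in active minutes, calibrated so the
#'   expected daily total hits the target), `activity_coupling` (bpm per
#'   steps/min), `fragmentation` (burst-length scale in \[0,1\]),
#'   `phase_shift` (h), `noise_sd` (bpm), `nonwear_rate` (h/day), and the
#'   activity-waveform parameters `p_min`, `p_max`, `act_alpha`, `act_beta`.
#' @export
group_profile <- function(group = .GROUPS) {
  group <- match.arg(group)
  base <- switch(group,
    robust = list(
      cosinor_truth = c(minimum = 58.8, amplitude = 16, alpha = -0.45,
                        beta = 12, acrophase = 14.0),
      daily_steps_target = 9080, p_max = 0.50, fragmentation = 0.15,
      phase_shift = 0, activity_coupling = 0.75, nonwear_rate = 1.0),
    prefrail = list(
      cosinor_truth = c(minimum = 57.2, amplitude = 20, alpha = -0.40,
                        beta = 12, acrophase = 13.8),
      daily_steps_target = 7809, p_max = 0.46, fragmentation = 0.35,
      phase_shift = 0, activity_coupling = 0.70, nonwear_rate = 1.3),
    frail = list(
      cosinor_truth = c(minimum = 61.7, amplitude = 15, alpha = -0.40,
                        beta = 12, acrophase = 14.5),
      daily_steps_target = 6005, p_max = 0.40, fragmentation = 0.60,
      phase_shift = 0.5, activity_coupling = 0.70, nonwear_rate = 1.6))
  profile <- c(base,
               list(group = group, p_min = 0.005, act_alpha = -0.45,
                    act_beta = 8, noise_sd = 3, ar_coef = 0.7))
  profile$activity_intensity <-
    profile$daily_steps_target / .expected_active_minutes(profile)
  structure(profile, class = "group_profile")
}

# active-probability waveform at clock hour t
.activity_prob <- function(profile, t) {
  phi <- profile$cosinor_truth[["acrophase"]] + profile$phase_shift
  profile$p_min + (profile$p_max - profile$p_min) *
    antilogistic(classic_cosine(t, phi), profile$act_alpha, profile$act_beta)
}

.expected_active_minutes <- function(profile) {
  t <- (0:1439) / 60
  sum(.activity_prob(profile, t))
}

#' Expected daily step total under a group profile
#'
#' Analytic expectation of the daily step sum: activity intensity times the
#' expected number of active minutes per day (the integral of the active
#' probability waveform over the 24-h minute grid).
#'
#' @param profile A [group_profile()].
#' @return Expected steps per day.
#' @export
expected_daily_steps <- function(profile) {
  profile$activity_intensity * .expected_active_minutes(profile)
}

#' Simulate one participant's minute-level recording
#'
#' Generates `days` full calendar days of minute-level steps and heart
#' rate from a [group_profile()]: a two-state rest/active Markov process
#' with geometric burst lengths (mean `10 + 60 * fragmentation` minutes)
#' whose occupancy follows the activity waveform; overdispersed
#' (negative-binomial) step counts in active minutes and 0 at rest; heart
#' rate = cosinor baseline + coupling x 5-minute rolling step rate + AR(1)
#' noise (lag-1 coefficient 0.7, innovation SD `noise_sd`); and Poisson-
#' placed non-wear blocks (mean length 45 min) masking both streams at
#' `nonwear_rate` hours/day.
#'
#' @param profile A [group_profile()] (or a modified copy).
#' @param days Number of full days to simulate (default 7).
#' @param seed Integer seed for this participant.
#' @param participant_id Identifier for the generated series.
#' @param start Date of the first simulated day.
#' @return list with `series` (a [participant_series()]) and `truth`
#'   (the realized generating parameters).
#' @export
simulate_participant <- function(profile, days = 7, seed = 1,
                                 participant_id = "SIM1",
                                 start = as.Date("2024-03-04")) {
  stopifnot(inherits(profile, "group_profile"), days >= 1)
  set.seed(seed)
  n <- days * 1440
  time <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC") +
    60 * (seq_len(n) - 1)
  t_clock <- ((seq_len(n) - 1) %% 1440) / 60
  p <- .activity_prob(profile, t_clock)

  # two-state Markov chain: leave-active rate 1/L_a gives geometric bursts
  # of mean length L_a; the rest->active rate tracks p(t) so that local
  # occupancy follows the activity waveform
  L_a <- 10 + 60 * profile$fragmentation
  q_a <- 1 / L_a
  q_r <- pmin(0.99, q_a * p / pmax(1 - p, 1e-6))
  u <- stats::runif(n)
  state <- logical(n)
  state[1] <- u[1] < p[1]
  for (i in 2:n) {
    state[i] <- if (state[i - 1]) u[i] >= q_a else u[i] < q_r[i]
  }

  steps <- numeric(n)
  n_act <- sum(state)
  if (n_act > 0 && profile$activity_intensity > 0) {
    steps[state] <- stats::rnbinom(n_act, size = 3,
                                   mu = profile$activity_intensity)
  }

  ct <- profile$cosinor_truth
  hr_base <- evaluate_cosinor(t_clock, ct[["minimum"]], ct[["amplitude"]],
                              ct[["alpha"]], ct[["beta"]], ct[["acrophase"]])
  recent <- as.numeric(stats::filter(steps, rep(1 / 5, 5), sides = 1))
  recent[1:4] <- cumsum(steps[1:4]) / (1:4)
  noise <- if (profile$noise_sd > 0) {
    as.numeric(stats::filter(stats::rnorm(n, sd = profile$noise_sd),
                             profile$ar_coef, method = "recursive"))
  } else numeric(n)
  hr <- pmax(35, hr_base + profile$activity_coupling * recent + noise)

  # non-wear blocks: Poisson count per day, geometric lengths (mean 45 min)
  if (profile$nonwear_rate > 0) {
    n_blocks <- stats::rpois(days, profile$nonwear_rate * 60 / 45)
    for (d in seq_len(days)) {
      if (n_blocks[d] == 0) next
      starts <- (d - 1) * 1440 + sample.int(1440, n_blocks[d])
      lens <- 1L + stats::rgeom(n_blocks[d], 1 / 45)
      for (k in seq_along(starts)) {
        idx <- starts[k]:min(n, starts[k] + lens[k] - 1L)
        hr[idx] <- NA_real_
        steps[idx] <- NA_real_
      }
    }
  }

  series <- participant_series(participant_id, time, steps, hr)
  truth <- c(list(participant_id = participant_id, group = profile$group,
                  days = days, seed = seed),
             as.list(ct),
             profile[c("activity_intensity", "activity_coupling",
                       "fragmentation", "phase_shift", "noise_sd",
                       "nonwear_rate")])
  list(series = series, truth = truth)
}

# planted frailty-item probabilities; the score-based classifier reproduces
# the planted label for >= 90% of draws
.draw_frailty_items <- function(group) {
  if (group == "frail") {
    base <- stats::rbinom(5, 1, 0.3)
    base[sample.int(5, 2)] <- 1L
  } else {
    base <- stats::rbinom(5, 1, 0.01)
    if (group == "prefrail") base[sample.int(5, 1)] <- 1L
  }
  base
}

#' Simulate a full cohort with questionnaire and ground truth
#'
#' Generates `sum(n_per_group)` participants (plus `n_excluded` extras whose
#' recordings hold only 4 full days, so they fail the 5-valid-day inclusion
#' rule), with group-dependent recording profiles and questionnaire records.
#' The word-list-memory score is generated as
#' `wlm = a0 - a_age * age - a_icv * (ICV.st x 100) + N(0, wlm_sd)` with the
#' step-based ICV computed from the generated recording, then clamped to
#' \[0, 20\].
#'
#' @param n_per_group Named counts for robust/prefrail/frail (default the
#'   study sizes 28/39/19).
#' @param days Recording length in days (default 7).
#' @param seed Master seed; each participant gets a child RNG stream, so
#'   cohorts are reproducible member-by-member.
#' @param n_excluded Extra participants planted to fail inclusion.
#' @param wlm_coef Coefficients `c(a0, age, icv100)` of the WLM generator
#'   (default `c(28.3, 0.15, 0.04)`).
#' @param wlm_sd Residual SD of the WLM score (default 2.5).
#' @return list with `series` (named list of [participant_series()]),
#'   `questionnaire` (data.frame as read by [read_questionnaire()]), and
#'   `truth` (data.frame of planted parameters incl. the planted group).
#' @export
simulate_cohort <- function(n_per_group = c(robust = 28, prefrail = 39,
                                            frail = 19),
                            days = 7, seed = 42, n_excluded = 0,
                            wlm_coef = c(a0 = 28.3, age = 0.15, icv100 = 0.04),
                            wlm_sd = 2.5) {
  stopifnot(all(n_per_group >= 1))
  groups <- rep(.GROUPS, times = n_per_group[.GROUPS])
  if (n_excluded > 0) {
    groups <- c(groups, rep(.GROUPS, length.out = n_excluded))
  }
  n_total <- length(groups)
  excluded <- c(rep(FALSE, sum(n_per_group)),
                rep(TRUE, n_excluded))
  ids <- sprintf("P%03d", seq_len(n_total))

  age_mean <- c(robust = 76.29, prefrail = 77.18, frail = 78.32)
  male_prob <- c(robust = 0.07, prefrail = 0.13, frail = 0.05)
  grip_mean <- c(robust = 23.84, prefrail = 24.61, frail = 22.11)
  walk_mean <- c(robust = 1.34, prefrail = 1.38, frail = 1.33)
  tmta_mean <- c(robust = 1.31, prefrail = 1.30, frail = 1.40)
  tmtb_mean <- c(robust = 3.04, prefrail = 3.42, frail = 3.09)
  dsst_mean <- c(robust = 46.96, prefrail = 45.56, frail = 39.58)

  series <- vector("list", n_total)
  qrows <- vector("list", n_total)
  trows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    g <- groups[i]
    profile <- group_profile(g)
    sim <- simulate_participant(profile,
                                days = if (excluded[i]) 4 else days,
                                seed = .child_seed(seed, i),
                                participant_id = ids[i])
    series[[i]] <- sim$series

    # questionnaire draws continue the participant's RNG stream
    items <- .draw_frailty_items(g)
    age <- min(95, max(65, stats::rnorm(1, age_mean[g], 5.7)))
    sex <- if (stats::runif(1) < male_prob[g]) "male" else "female"
    icv100 <- tryCatch({
      ds <- compute_valid_days(sim$series)
      ds <- hourly_aggregate(sim$series, ds)
      100 * as.numeric(intradaily_cv(ds$hourly_steps))
    }, error = function(e) NA_real_)
    wlm_mu <- wlm_coef[["a0"]] - wlm_coef[["age"]] * age -
      wlm_coef[["icv100"]] * ifelse(is.na(icv100), 110, icv100)
    wlm <- min(20, max(0, wlm_mu + stats::rnorm(1, sd = wlm_sd)))
    qrows[[i]] <- data.frame(
      participant_id = ids[i], age = round(age, 1), sex = sex,
      lives_alone = items[1], no_daily_conversation = items[2],
      not_feeling_helpful = items[3], going_out_less = items[4],
      not_visiting_friends = items[5],
      grip_strength = round(max(5, stats::rnorm(1, grip_mean[g], 5.4)), 1),
      walking_speed = round(max(0.3, stats::rnorm(1, walk_mean[g], 0.29)), 2),
      wlm = round(wlm, 1),
      tmt_a = round(max(0.4, stats::rnorm(1, tmta_mean[g], 0.34)), 2),
      tmt_b = round(max(0.8, stats::rnorm(1, tmtb_mean[g], 1.5)), 2),
      dsst = round(max(5, stats::rnorm(1, dsst_mean[g], 13.0))))
    trows[[i]] <- data.frame(
      participant_id = ids[i], group = g, excluded = excluded[i],
      icv100_true = icv100, wlm_mu = wlm_mu,
      as.data.frame(as.list(profile$cosinor_truth)),
      fragmentation = profile$fragmentation,
      activity_intensity = profile$activity_intensity,
      activity_coupling = profile$activity_coupling)
  }
  names(series) <- ids
  list(series = series,
       questionnaire = do.call(rbind, qrows),
       truth = do.call(rbind, trows))
}

#' Simulate a multinomial-logit frailty outcome with a planted effect
#'
#' Draws a scaled covariate (e.g. ICV x 100) and assigns group labels from
#' a three-level multinomial logit with the robust level as reference, for
#' effect-recovery studies on [multinomial_frailty_model()].
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param x_mean,x_sd Covariate distribution (default 110, 15 - the scale
#'   of ICV x 100).
#' @param intercepts,slopes Length-2 vectors (prefrail, frail): planted
#'   log-odds intercepts and per-unit log-OR slopes vs robust.
#' @return data.frame with `icv100` and `group` (factor, robust reference).
#' @export
simulate_multinomial_cohort <- function(n = 300, seed = 1,
                                        x_mean = 110, x_sd = 15,
                                        intercepts = c(prefrail = 0,
                                                       frail = -4.4),
                                        slopes = c(prefrail = 0,
                                                   frail = 0.04)) {
  set.seed(seed)
  x <- stats::rnorm(n, x_mean, x_sd)
  eta_pre <- intercepts[[1]] + slopes[[1]] * x
  eta_fra <- intercepts[[2]] + slopes[[2]] * x
  den <- 1 + exp(eta_pre) + exp(eta_fra)
  pr <- cbind(robust = 1 / den, prefrail = exp(eta_pre) / den,
              frail = exp(eta_fra) / den)
  g <- apply(pr, 1, function(p) sample(.GROUPS, 1, prob = p))
  data.frame(icv100 = x, group = factor(g, levels = .GROUPS))
}
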