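pattern24 <- function() 50 + 40 * sin(2 * pi * (0:23) / 24)

test_that("IS is 1 for identical days and 0 for antiperiodic shifted days", {
  m <- matrix(rep(pattern24(), 3), nrow = 3, byrow = TRUE)
  rownames(m) <- as.character(as.Date("2024-03-04") + 0:2)
  expect_equal(as.numeric(interdaily_stability(m)), 1)

  # 12h-antiperiodic pattern; day 2 shifted 12 h -> every clock-hour mean
  # equals the grand mean
  pat <- rep(c(10, 90), each = 12)
  m2 <- rbind(pat, c(pat[13:24], pat[1:12]))
  rownames(m2) <- as.character(as.Date("2024-03-04") + 0:1)
  expect_equal(as.numeric(interdaily_stability(m2)), 0)

  expect_true(is.na(interdaily_stability(matrix(5, 3, 24))))
})

test_that("IS and IV match brute-force evaluation on random matrices", {
  set.seed(31)
  for (rep in 1:50) {
    m <- random_hourly(days = sample(2:5, 1),
                       missing_frac = sample(c(0, 0.1), 1))
    expect_equal(as.numeric(interdaily_stability(m)), oracle_is(m),
                 tolerance = 1e-12)
    expect_equal(as.numeric(intradaily_variability(m)), oracle_iv(m),
                 tolerance = 1e-12)
  }
})

test_that("IV has its closed-form values on alternating and cosine series", {
  alt <- matrix(rep(c(100, 300), 24), nrow = 2, byrow = TRUE)
  rownames(alt) <- as.character(as.Date("2024-03-04") + 0:1)
  expect_equal(as.numeric(intradaily_variability(alt)), 4)

  cosm <- matrix(rep(100 + 50 * cos(2 * pi * (0:23) / 24), 4),
                 nrow = 4, byrow = TRUE)
  rownames(cosm) <- as.character(as.Date("2024-03-04") + 0:3)
  # trig identity: sum of squared successive cosine differences gives
  # IV -> 2 * (1 - cos(pi / 12)) as the day count grows; exact here up to
  # the N/(m) and N/(N-1) factors
  iv <- as.numeric(intradaily_variability(cosm))
  expect_equal(iv, 2 * (1 - cos(pi / 12)), tolerance = 0.02)
})

test_that("IS stays in [0,1] and IV non-negative on random inputs", {
  set.seed(32)
  for (rep in 1:100) {
    m <- random_hourly(days = sample(2:6, 1))
    is_val <- as.numeric(interdaily_stability(m))
    expect_gte(is_val, 0)
    expect_lte(is_val, 1 + 1e-12)
    expect_gte(as.numeric(intradaily_variability(m)), 0)
  }
})

test_that("M10/L5/RA agree with the exhaustive window scan", {
  flat <- rep(1, 24)
  r <- m10_l5_ra(flat)
  expect_equal(r$m10, 1)
  expect_equal(r$l5, 1)
  expect_equal(as.numeric(r$ra), 0)

  # night 22:00-08:00 at 0, day 600: M10 = 600, L5 = 0, RA = 1
  stepprof <- ifelse(0:23 >= 22 | 0:23 < 8, 0, 600)
  r2 <- m10_l5_ra(stepprof)
  expect_equal(r2$m10, 600)
  expect_equal(r2$l5, 0)
  expect_equal(as.numeric(r2$ra), 1)

  set.seed(33)
  for (rep in 1:200) {
    prof <- rgamma(24, 2, 0.1)
    r3 <- m10_l5_ra(prof)
    o <- oracle_m10_l5(prof)
    expect_equal(r3$m10, unname(o["m10"]))
    expect_equal(r3$l5, unname(o["l5"]))
    expect_equal(as.numeric(r3$ra),
                 unname((o["m10"] - o["l5"]) / (o["m10"] + o["l5"])))
  }

  expect_true(is.na(m10_l5_ra(c(NA, rep(1, 23)))$m10))
})

test_that("ICV is 0 for identical days and matches hand computation", {
  ident <- matrix(rep(pattern24(), 4), nrow = 4, byrow = TRUE)
  expect_equal(as.numeric(intradaily_cv(ident)), 0)

  two <- rbind(rep(100, 24), rep(300, 24))
  expect_equal(as.numeric(intradaily_cv(two)), sd(c(100, 300)) / 200)

  set.seed(34)
  for (rep in 1:30) {
    m <- random_hourly(days = 4, missing_frac = sample(c(0, 0.15), 1))
    expect_equal(as.numeric(intradaily_cv(m)), oracle_icv(m),
                 tolerance = 1e-12)
  }
})

test_that("ICV is scale invariant", {
  set.seed(35)
  m <- random_hourly(days = 5)
  base <- as.numeric(intradaily_cv(m))
  for (c in c(0.2, 3, 117)) {
    expect_equal(as.numeric(intradaily_cv(c * m)), base, tolerance = 1e-12)
  }
})

test_that("fragmented activity yields higher ICV than regular activity", {
  frag <- group_profile("frail")
  reg <- group_profile("robust")
  vals <- sapply(1:8, function(i) {
    sf <- simulate_participant(frag, days = 5, seed = 100 + i,
                               participant_id = "F")$series
    sr <- simulate_participant(reg, days = 5, seed = 200 + i,
                               participant_id = "R")$series
    c(frail = as.numeric(intradaily_cv(hourly_from_series(sf)$hourly_steps)),
      robust = as.numeric(intradaily_cv(hourly_from_series(sr)$hourly_steps)))
  })
  expect_gt(mean(vals["frail", ]), mean(vals["robust", ]))
})

test_that("day-lagged autocorrelation is 1 for periodic signals and near 0 for noise", {
  h <- ((0:(7 * 1440 - 1)) %% 1440) / 60
  per <- 100 + 50 * cos(2 * pi * h / 24)
  for (bin in c(15, 30, 60)) {
    expect_equal(as.numeric(day_lag_autocorrelation(per, bin)), 1,
                 tolerance = 1e-9)
  }
  set.seed(36)
  noise <- rnorm(7 * 1440, 100, 20)
  for (bin in c(15, 30, 60)) {
    n_pairs <- 6 * 1440 / bin
    expect_lt(abs(as.numeric(day_lag_autocorrelation(noise, bin))),
              2 / sqrt(n_pairs))
  }
})

test_that("day-lagged autocorrelation matches the brute-force oracle", {
  set.seed(37)
  v <- rnorm(3 * 1440, 50, 5)
  v[2000 + 1:120] <- v[2000 + 1:120] + 60          # shared bump, day 2
  v[2000 + 1440 + 1:120] <- v[2000 + 1440 + 1:120] + 60
  v[sample(length(v), 400)] <- NA
  for (bin in c(15, 30, 60)) {
    expect_equal(as.numeric(day_lag_autocorrelation(v, bin)),
                 oracle_daylag_cor(v, bin), tolerance = 1e-12)
  }
})

test_that("day-lagged autocorrelation is shift invariant", {
  set.seed(38)
  v <- rgamma(2 * 1440 + 600, 3, 0.1)
  base <- as.numeric(day_lag_autocorrelation(v, 30))
  expect_equal(as.numeric(day_lag_autocorrelation(v + 1000, 30)), base,
               tolerance = 1e-9)
})

test_that("the robust z-score detector counts injected bursts and skips gaps", {
  days <- 5
  n <- days * 1440
  v <- rep(10, n)
  dates <- rep(as.Date("2024-03-04") + 0:(days - 1), each = 1440)
  for (d in 0:(days - 1)) {
    for (h0 in c(9, 13, 17)) v[d * 1440 + h0 * 60 + 1:30] <- 100
  }
  r <- robust_peak_counts(v, dates)
  expect_equal(r$peaks_mean, 3)
  expect_equal(r$peaks_sd, 0)

  # constant series: no peaks anywhere
  rc <- robust_peak_counts(rep(10, n), dates)
  expect_equal(rc$peaks_mean, 0)

  # delete 10% of minutes at random: the skip logic keeps all bursts
  set.seed(39)
  v2 <- v
  v2[sample(n, n / 10)] <- NA
  r2 <- robust_peak_counts(v2, dates)
  expect_equal(r2$peaks_mean, 3)
})
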