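#' Classic 24-hour cosine wave
#'
#' `c(t) = cos((t - phi) * pi / 12)`: period 24 h, peak at `t = phi`.
#'
#' @param t Clock time in decimal hours.
#' @param acrophase Peak time phi in hours.
#' @return Value in \[-1, 1\].
#' @export
classic_cosine <- function(t, acrophase) {
  cos((t - acrophase) * pi / 12)
}

#' Antilogistic (sigmoid) transform
#'
#' `l(c) = exp(beta * (c - alpha)) / (1 + exp(beta * (c - alpha)))`,
#' evaluated stably for large `|beta * (c - alpha)|`. `alpha` sets where on
#' the cosine the half-rise sits (peak width); `beta` the steepness of the
#' rise and fall (large beta approaches a square wave).
#'
#' @param c Cosine value in \[-1, 1\].
#' @param alpha Width parameter in (-1, 1).
#' @param beta Steepness parameter > 0.
#' @return Value in (0, 1).
#' @export
antilogistic <- function(c, alpha, beta) {
  stopifnot(beta > 0)
  stats::plogis(beta * (c - alpha))
}

#' Evaluate the extended cosinor curve
#'
#' `r(t) = min + amp * l(c(t))` with `c(t)` the classic cosine
#' ([classic_cosine()]) and `l` the antilogistic transform
#' ([antilogistic()]). At `c(t) = alpha` the curve passes through
#' `min + amp/2`, the MESOR.
#'
#' @param t Clock time in decimal hours.
#' @param minimum,amplitude,alpha,beta,acrophase The five model parameters.
#' @return Fitted value(s) in stream units.
#' @export
evaluate_cosinor <- function(t, minimum, amplitude, alpha, beta, acrophase) {
  stopifnot(amplitude >= 0)
  minimum + amplitude * antilogistic(classic_cosine(t, acrophase), alpha, beta)
}

#' Derived rhythm phase metrics from the five core parameters
#'
#' `MESOR = minimum + amplitude / 2` (rhythm midline of the extended
#' model); `UpMesor`/`DownMesor` are the clock times where the fitted curve
#' crosses the MESOR ascending and descending:
#' `acrophase -/+ (12/pi) * arccos(alpha) (mod 24)`; `acrotime` is the
#' acrophase expressed as a clock hour.
#'
#' @param minimum,amplitude,alpha,acrophase Fitted parameters (`beta` does
#'   not enter the crossings).
#' @return list with `mesor`, `up_mesor`, `down_mesor`, `acrotime`.
#' @export
derive_phase_metrics <- function(minimum, amplitude, alpha, acrophase) {
  mesor <- minimum + amplitude / 2
  if (is.na(alpha) || abs(alpha) >= 1) {
    na <- .undefined("|alpha| >= 1: no MESOR crossing")
    return(list(mesor = mesor, up_mesor = na, down_mesor = na,
                acrotime = .mod24(acrophase)))
  }
  half_width <- (12 / pi) * acos(alpha)
  list(mesor = mesor,
       up_mesor = .mod24(acrophase - half_width),
       down_mesor = .mod24(acrophase + half_width),
       acrotime = .mod24(acrophase))
}

#' Fit the extended (antilogistic) cosinor model
#'
#' Minimizes the residual sum of squares of
#' `r(t) = min + amp * l(c(t))` over (minimum, amplitude, alpha, beta,
#' acrophase), pooling all observations with time-of-day as the sole
#' predictor. Initialization comes from the closed-form linear cosinor
#' (cos/sin regression) with `alpha = 0`, `beta = 2`; a multi-start over 4
#' acrophase offsets (0, 6, 12, 18 h) guards against phase-reflection local
#' minima. Bounds: `amplitude >= 0`, `alpha` in (-0.999, 0.999), `beta` in
#' (0.001, 100]; the acrophase is unconstrained during optimization (the
#' model is 24 h periodic) and reported mod 24.
#'
#' The pseudo-F statistic compares the fit against the intercept-only null:
#' `F_pseudo = ((RSS0 - RSS)/4) / (RSS/(n - 5))`.
#'
#' @param time Observation times in decimal clock hours (day pooled).
#' @param values Observed stream values (NA dropped).
#' @param beta_max Upper bound for the steepness parameter (default 100).
#' @param degenerate_tol Fits with `amplitude < degenerate_tol * sd(values)`
#'   are flagged degenerate and phase metrics withheld (default 0.05).
#' @param f_min Fits whose pseudo-F falls below `f_min` are likewise flagged
#'   degenerate (default 10): the rhythm explains essentially nothing, so
#'   amplitude and phase are noise artefacts.
#' @return A `cosinor_fit`: list with the five parameters, derived
#'   `mesor`, `up_mesor`, `down_mesor`, `acrotime`, `f_pseudo`, `rss`,
#'   `n_obs`, `converged`, `degenerate`.
#' @export
fit_extended_cosinor <- function(time, values, beta_max = 100,
                                 degenerate_tol = 0.05, f_min = 10) {
  ok <- !is.na(values) & !is.na(time)
  t <- as.numeric(time)[ok]
  x <- as.numeric(values)[ok]
  n <- length(x)
  if (n < 10) stop("too few observations for a cosinor fit (need >= 10)")
  sd_x <- stats::sd(x)
  rss0 <- sum((x - mean(x))^2)
  if (sd_x == 0) {
    return(.cosinor_result(c(x[1], 0, 0, 2, 0), rss = 0, rss0 = 0, n = n,
                           converged = TRUE, degenerate = TRUE))
  }

  # closed-form linear cosinor for the starting point
  cc <- cos(2 * pi * t / 24)
  ss <- sin(2 * pi * t / 24)
  lin <- stats::lm.fit(cbind(1, cc, ss), x)
  a <- lin$coefficients[2]
  b <- lin$coefficients[3]
  amp0 <- max(2 * sqrt(a^2 + b^2), 0.01 * sd_x)
  phi0 <- .mod24(atan2(b, a) * 12 / pi)
  min0 <- lin$coefficients[1] - amp0 / 2

  obj <- function(p) {
    r <- evaluate_cosinor(t, p[1], p[2], p[3], p[4], p[5])
    sum((x - r)^2)
  }
  grad <- function(p) {
    cw <- classic_cosine(t, p[5])
    L <- stats::plogis(p[4] * (cw - p[3]))
    r <- p[1] + p[2] * L
    e <- x - r
    dL <- L * (1 - L)
    common <- p[2] * dL
    c(-2 * sum(e),
      -2 * sum(e * L),
      -2 * sum(e * common * (-p[4])),
      -2 * sum(e * common * (cw - p[3])),
      -2 * sum(e * common * p[4] * sin((t - p[5]) * pi / 12) * pi / 12))
  }
  lower <- c(-Inf, 0, -0.999, 1e-3, -Inf)
  upper <- c(Inf, Inf, 0.999, beta_max, Inf)
  best <- NULL
  for (off in c(0, 6, 12, 18)) {
    start <- c(min0, amp0, 0, 2, phi0 + off)
    fit <- tryCatch(
      stats::nlminb(start, obj, gradient = grad, lower = lower, upper = upper,
                    control = list(abs.tol = 1e-8, rel.tol = 1e-10,
                                   iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) {
    return(.cosinor_result(rep(NA_real_, 5), rss = NA_real_, rss0 = rss0,
                           n = n, converged = FALSE, degenerate = FALSE))
  }
  converged <- best$convergence == 0 ||
    grepl("relative convergence|singular convergence|X-convergence|both X",
          best$message)
  rss <- best$objective
  f_pseudo <- if (rss > 0 && n > 5) ((rss0 - rss) / 4) / (rss / (n - 5)) else
    Inf
  degenerate <- best$par[2] < degenerate_tol * sd_x || f_pseudo < f_min
  .cosinor_result(best$par, rss = rss, rss0 = rss0, n = n,
                  converged = converged, degenerate = degenerate)
}

.cosinor_result <- function(par, rss, rss0, n, converged, degenerate) {
  minimum <- par[1]; amplitude <- par[2]
  alpha <- par[3]; beta <- par[4]
  acro <- .mod24(par[5])
  f_pseudo <- if (!is.na(rss) && rss > 0 && n > 5) {
    ((rss0 - rss) / 4) / (rss / (n - 5))
  } else NA_real_
  phase <- if (converged && !degenerate && !anyNA(par)) {
    derive_phase_metrics(minimum, amplitude, alpha, acro)
  } else {
    list(mesor = minimum + amplitude / 2, up_mesor = NA_real_,
         down_mesor = NA_real_, acrotime = NA_real_)
  }
  structure(
    list(minimum = unname(minimum), amplitude = unname(amplitude),
         alpha = unname(alpha), beta = unname(beta),
         acrophase_rad = unname(.mod24(acro) * pi / 12),
         acrotime = unname(phase$acrotime),
         mesor = unname(phase$mesor),
         up_mesor = unname(phase$up_mesor),
         down_mesor = unname(phase$down_mesor),
         f_pseudo = unname(f_pseudo),
         rss = unname(rss), n_obs = n,
         converged = converged, degenerate = degenerate),
    class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat("<cosinor_fit> n =", x$n_obs,
      if (!x$converged) "(NOT converged)" else "",
      if (x$degenerate) "(degenerate: amplitude ~ 0)" else "", "\n")
  cat(sprintf("  minimum %.3f  amplitude %.3f  alpha %.3f  beta %.3f\n",
              x$minimum, x$amplitude, x$alpha, x$beta))
  cat(sprintf("  acrotime %.2f h  MESOR %.3f  UpMesor %.2f  DownMesor %.2f  F_pseudo %.1f\n",
              x$acrotime, x$mesor,
              ifelse(is.na(x$up_mesor), NA, x$up_mesor),
              ifelse(is.na(x$down_mesor), NA, x$down_mesor), x$f_pseudo))
  invisible(x)
}

#' Plot an extended cosinor fit against observed hourly means
#'
#' Diagnostic plot: observed hourly means of the fitted stream with the
#' fitted extended cosinor curve overlaid. Requires ggplot2.
#'
#' @param fit A `cosinor_fit`.
#' @param time,values The data the model was fitted to.
#' @return A ggplot object.
#' @export
plot_cosinor_fit <- function(fit, time, values) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ok <- !is.na(values)
  hr <- floor(time[ok] %% 24)
  obs <- data.frame(hour = sort(unique(hr)))
  obs$mean <- tapply(values[ok], hr, mean)[as.character(obs$hour)]
  grid <- data.frame(t = seq(0, 24, by = 0.1))
  grid$fit <- evaluate_cosinor(grid$t, fit$minimum, fit$amplitude,
                               fit$alpha, fit$beta, fit$acrotime)
  obs$hour_mid <- obs$hour + 0.5
  ggplot2::ggplot() +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(x = hour_mid, y = mean)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = t, y = fit),
                       color = "forestgreen") +
    ggplot2::labs(x = "clock hour", y = "stream value") +
    ggplot2::theme_minimal()
}
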