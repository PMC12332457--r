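# Cohort-level statistics: social frailty classification, normality-gated
# correlation matrices, Kruskal-Wallis + Dunn post hoc tests (Bonferroni
# over the three pairwise contrasts), OLS on the word-list-memory score,
# and multinomial logistic models with the robust group as reference.

#' Classify the social frailty index
#'
#' Score = sum of the five items (living alone; no daily conversation; not
#' feeling helpful; going out less; not visiting friends). Score 0 =
#' robust, 1 = social prefrailty, 2-5 = social frailty.
#'
#' @param questionnaire data.frame from [read_questionnaire()] (or any
#'   table with `participant_id` and the five 0/1 item columns).
#' @return data.frame with `participant_id`, `score`, `group` (factor with
#'   levels robust/prefrail/frail; NA when an item is missing).
#' @export
classify_frailty <- function(questionnaire) {
  items <- as.matrix(questionnaire[, .FRAILTY_ITEMS, drop = FALSE])
  score <- rowSums(items)
  group <- cut(score, breaks = c(-0.5, 0.5, 1.5, 5.5),
               labels = .GROUPS)
  group <- factor(as.character(group), levels = .GROUPS)
  data.frame(participant_id = questionnaire$participant_id,
             score = as.integer(score), group = group,
             stringsAsFactors = FALSE)
}

#' Normality-gated correlation matrix
#'
#' Pairwise-complete correlations between feature columns: Pearson only
#' when both variables pass the Shapiro-Wilk normality test at `alpha`,
#' Spearman rank correlation otherwise. Optionally computed within each
#' group as well as for the whole cohort.
#'
#' @param features data.frame of numeric feature columns.
#' @param vars Columns to correlate (default: all numeric columns).
#' @param alpha Shapiro-Wilk significance gate (default 0.05).
#' @param group Optional factor splitting the cohort; per-level matrices
#'   are returned under `by_group`.
#' @return list with `r`, `p`, `method` matrices (and `by_group` when
#'   `group` is given). Constant variables give NA cells.
#' @export
correlation_matrix <- function(features, vars = NULL, alpha = 0.05,
                               group = NULL) {
  if (is.null(vars)) {
    vars <- names(features)[vapply(features, is.numeric, logical(1))]
  }
  x <- features[, vars, drop = FALSE]
  out <- .cor_gate(x, alpha)
  if (!is.null(group)) {
    out$by_group <- lapply(split(x, group), .cor_gate, alpha = alpha)
  }
  out
}

.cor_gate <- function(x, alpha) {
  vars <- names(x)
  k <- length(vars)
  normal <- vapply(vars, function(v) {
    vv <- x[[v]][!is.na(x[[v]])]
    if (length(vv) < 3 || length(unique(vv)) < 3) return(FALSE)
    tryCatch(stats::shapiro.test(vv)$p.value > alpha,
             error = function(e) FALSE)
  }, logical(1))
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  method <- matrix(NA_character_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    for (j in seq_len(i)) {
      a <- x[[i]]; b <- x[[j]]
      ok <- !is.na(a) & !is.na(b)
      m <- if (normal[i] && normal[j]) "pearson" else "spearman"
      method[i, j] <- method[j, i] <- m
      if (sum(ok) < 4 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(a[ok], b[ok], method = m, exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  diag(p) <- 0
  list(r = r, p = p, method = method)
}

#' Kruskal-Wallis with Dunn post hoc tests
#'
#' For each variable: Kruskal-Wallis H (tie-corrected) across the three
#' frailty groups, then Dunn z statistics for the three pairwise contrasts
#' with Bonferroni adjustment (factor 3, capped at 1), plus per-group
#' medians and IQRs. Variables with any group holding fewer than 2
#' observations are skipped with a message.
#'
#' @param features data.frame of feature columns.
#' @param group Factor with levels robust/prefrail/frail.
#' @param vars Variables to test (default: all numeric columns).
#' @return data.frame, one row per variable: medians/IQRs, `H`,
#'   `p_overall`, and raw + adjusted p for the three contrasts.
#' @export
kruskal_dunn <- function(features, group, vars = NULL) {
  if (is.null(vars)) {
    vars <- names(features)[vapply(features, is.numeric, logical(1))]
  }
  group <- factor(group)
  rows <- lapply(vars, function(v) {
    x <- features[[v]]
    ok <- !is.na(x) & !is.na(group)
    x <- x[ok]; g <- droplevels(group[ok])
    if (nlevels(g) < 2 || any(table(g) < 2)) {
      message("kruskal_dunn: skipping '", v,
              "' (a group has fewer than 2 observations)")
      return(NULL)
    }
    if (length(unique(x)) == 1) {
      # all observations tied: no evidence of any group difference
      kw <- list(statistic = 0, p.value = 1)
      dunn <- .dunn_test_null(g)
    } else {
      kw <- stats::kruskal.test(x, g)
      dunn <- .dunn_test(x, g)
    }
    med <- tapply(x, g, stats::median)
    iqr <- tapply(x, g, stats::IQR)
    row <- data.frame(variable = v, H = unname(kw$statistic),
                      p_overall = kw$p.value)
    for (lev in levels(g)) {
      row[[paste0("median_", lev)]] <- unname(med[lev])
      row[[paste0("iqr_", lev)]] <- unname(iqr[lev])
    }
    for (k in seq_len(nrow(dunn))) {
      nm <- paste0(dunn$a[k], "_vs_", dunn$b[k])
      row[[paste0("z_", nm)]] <- dunn$z[k]
      row[[paste0("p_", nm)]] <- dunn$p[k]
      row[[paste0("p_adj_", nm)]] <- dunn$p_adj[k]
    }
    row
  })
  do.call(rbind, rows)
}

.dunn_test_null <- function(g) {
  pairs <- utils::combn(levels(g), 2)
  data.frame(a = pairs[1, ], b = pairs[2, ], z = 0, p = 1, p_adj = 1)
}

# Dunn (1964) pairwise z on joint ranks with tie correction; Bonferroni by
# the number of contrasts
.dunn_test <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ng <- table(g)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  sigma2 <- n * (n + 1) / 12 - tie_corr
  levs <- levels(g)
  pairs <- utils::combn(levs, 2)
  m <- ncol(pairs)
  z <- numeric(m)
  for (k in seq_len(m)) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt(sigma2 * (1 / ng[[a]] + 1 / ng[[b]]))
    z[k] <- (rbar[[a]] - rbar[[b]]) / se
  }
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(a = pairs[1, ], b = pairs[2, ], z = z, p = p,
             p_adj = pmin(1, m * p))
}

#' Linear regression on the word-list-memory score
#'
#' Ordinary least squares with WLM as the outcome. The step-based ICV is
#' entered scaled by 100 (column `ICV.st.x100` created on the fly from
#' `ICV.st` when requested). Reports per-term beta, SE, 95% CI and p, plus
#' R-squared, adjusted R-squared and the overall F-test p.
#'
#' @param data Analysis table (see [build_feature_table()]) containing
#'   `wlm` and the requested terms.
#' @param terms Character vector of predictor columns; `"ICV.st"` is
#'   automatically replaced by its x100 version.
#' @return list with `coefficients` (data.frame) and `fit`
#'   (`r_squared`, `adj_r_squared`, `f_p_value`, `n`).
#' @export
linear_model_wlm <- function(data, terms = c("age", "ICV.st")) {
  df <- data
  terms2 <- terms
  if ("ICV.st" %in% terms2) {
    df$ICV.st.x100 <- df$ICV.st * 100
    terms2[terms2 == "ICV.st"] <- "ICV.st.x100"
  }
  use <- stats::complete.cases(df[, c("wlm", terms2), drop = FALSE])
  # (complete cases over the outcome alone when no terms are requested)
  df <- df[use, , drop = FALSE]
  if (nrow(df) < length(terms2) + 2) stop("too few complete cases")
  rhs <- if (length(terms2) == 0) "1" else paste(terms2, collapse = " + ")
  fml <- stats::as.formula(paste("wlm ~", rhs))
  fit <- stats::lm(fml, data = df)
  if (fit$rank < length(terms2) + 1) {
    al <- stats::alias(fit)$Complete
    stop("rank-deficient model; collinear terms: ",
         paste(rownames(al), collapse = ", "))
  }
  sm <- summary(fit)
  ci <- stats::confint(fit)
  co <- data.frame(term = rownames(sm$coefficients),
                   beta = sm$coefficients[, 1],
                   se = sm$coefficients[, 2],
                   ci_low = ci[, 1], ci_high = ci[, 2],
                   p = sm$coefficients[, 4],
                   row.names = NULL)
  f_p <- if (length(terms2) == 0 || is.null(sm$fstatistic)) NA_real_ else
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)
  list(coefficients = co,
       fit = list(r_squared = sm$r.squared,
                  adj_r_squared = sm$adj.r.squared,
                  f_p_value = unname(f_p), n = nrow(df)))
}

#' Multinomial logistic model of frailty group
#'
#' Maximum-likelihood multinomial logit (robust group as reference; two
#' equations: prefrail vs robust and frail vs robust) on complete cases.
#' Scaled covariates are created on the fly: `ICV.st` and `alpha.hr` terms
#' enter x100 as in the published tables. Reports per-term beta, SE,
#' OR = exp(beta), Wald 95% CI and p, with whole-model fit via the
#' likelihood-ratio test against the intercept-only model, Nagelkerke
#' R-squared `(1 - (L0/L1)^(2/n)) / (1 - L0^(2/n))`, and AIC. Apparent
#' separation (any |beta| > 15) flags the model and withholds estimates.
#'
#' @param data Analysis table with a `group` factor
#'   (robust/prefrail/frail) and the predictor columns.
#' @param terms Predictor columns; `"ICV.st"` and `"alpha.hr"` are
#'   automatically scaled x100.
#' @param adjust `"none"` or `"age_sex"` (adds `age` and `sex`).
#' @return list with `coefficients` (data.frame: outcome, term, beta, se,
#'   or, ci_low, ci_high, p), `fit` (`lr_p_value`, `nagelkerke_r2`, `aic`,
#'   `n`), and `separation` flag.
#' @export
multinomial_frailty_model <- function(data, terms,
                                      adjust = c("none", "age_sex")) {
  adjust <- match.arg(adjust)
  df <- data
  terms2 <- terms
  if ("ICV.st" %in% terms2) {
    df$ICV.st.x100 <- df$ICV.st * 100
    terms2[terms2 == "ICV.st"] <- "ICV.st.x100"
  }
  if ("alpha.hr" %in% terms2) {
    df$alpha.hr.x100 <- df$alpha.hr * 100
    terms2[terms2 == "alpha.hr"] <- "alpha.hr.x100"
  }
  if (adjust == "age_sex") terms2 <- c("age", "sex", terms2)
  stopifnot("group" %in% names(df))
  df$group <- factor(df$group, levels = .GROUPS)
  use <- stats::complete.cases(df[, c("group", terms2), drop = FALSE])
  n_dropped <- sum(!use)
  if (n_dropped > 0) {
    message("multinomial_frailty_model: dropped ", n_dropped,
            " incomplete case(s)")
  }
  df <- df[use, , drop = FALSE]
  if (nlevels(droplevels(df$group)) < 3) {
    stop("all three groups must be represented")
  }
  fml <- stats::as.formula(paste("group ~", paste(terms2, collapse = " + ")))
  fit <- nnet::multinom(fml, data = df, trace = FALSE, maxit = 500)
  null_fit <- nnet::multinom(group ~ 1, data = df, trace = FALSE)

  b <- coef(fit)           # 2 x (terms + intercept)
  se <- tryCatch({
    v <- vcov(fit)
    matrix(sqrt(diag(v)), nrow = nrow(b), byrow = TRUE,
           dimnames = dimnames(b))
  }, error = function(e) b * NA_real_)
  separation <- any(abs(b) > 15, na.rm = TRUE)
  zq <- stats::qnorm(0.975)
  co <- do.call(rbind, lapply(rownames(b), function(lev) {
    data.frame(outcome = lev, term = colnames(b),
               beta = b[lev, ], se = se[lev, ],
               or = exp(b[lev, ]),
               ci_low = exp(b[lev, ] - zq * se[lev, ]),
               ci_high = exp(b[lev, ] + zq * se[lev, ]),
               p = 2 * stats::pnorm(-abs(b[lev, ] / se[lev, ])),
               row.names = NULL)
  }))
  if (separation) {
    co[, c("beta", "se", "or", "ci_low", "ci_high", "p")] <- NA_real_
  }
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(null_fit))
  df_diff <- attr(stats::logLik(fit), "df") - attr(stats::logLik(null_fit),
                                                   "df")
  n <- nrow(df)
  lr_p <- stats::pchisq(2 * (ll1 - ll0), df_diff, lower.tail = FALSE)
  nagelkerke <- (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
  list(coefficients = co,
       fit = list(lr_p_value = lr_p, nagelkerke_r2 = nagelkerke,
                  aic = stats::AIC(fit), n = n),
       separation = separation)
}

#' Assemble the analysis table
#'
#' Joins the per-participant feature table, the frailty classification and
#' the questionnaire on `participant_id`, keeping only included
#' participants (those passing the 5-valid-day rule); dropped and orphan
#' rows are counted in a message.
#'
#' @param features data.frame from [extract_cohort_features()] (must carry
#'   `included`).
#' @param classification data.frame from [classify_frailty()].
#' @param questionnaire data.frame from [read_questionnaire()].
#' @return data.frame, one row per included participant.
#' @export
build_feature_table <- function(features, classification, questionnaire) {
  if (anyDuplicated(features$participant_id)) {
    stop("duplicate participant_id in features")
  }
  if (anyDuplicated(questionnaire$participant_id)) {
    stop("duplicate participant_id in questionnaire")
  }
  if (nrow(features) == 0) {
    warning("empty feature store")
    return(features)
  }
  n_excluded <- sum(!features$included)
  kept <- features[features$included, , drop = FALSE]
  merged <- merge(kept, classification, by = "participant_id")
  merged <- merge(merged, questionnaire, by = "participant_id")
  n_orphan <- nrow(kept) - nrow(merged)
  message("build_feature_table: ", nrow(merged), " included, ",
          n_excluded, " excluded by the valid-day rule, ",
          n_orphan, " dropped in the join")
  merged
}
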