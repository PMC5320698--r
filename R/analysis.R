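#' Univariate and multivariable progression models
#'
#' Reproduces the cohort analysis stage: ordinary least squares of follow-up
#' WMH volume on each predictor separately (univariate) and on all
#' predictors jointly (multivariable), on complete cases only. Coefficients
#' are ml of follow-up volume per unit of predictor, with 95 percent
#' confidence intervals and p-values.
#'
#' @param cohort A `wmh_cohort` (or plain data frame with the cohort
#'   columns) containing follow-up volumes for at least some rows.
#' @param predictors Character vector of predictor names (default all ten,
#'   see [progression_predictors()]).
#' @return An object of class `wmh_progression_fits`: list with elements
#'   `univariate` (data frame, one row per predictor), `multivariable`
#'   (data frame plus attributes), `r_squared`, `resid_sd`, `n`.
#' @export
fit_progression_models <- function(cohort, predictors = progression_predictors()) {
  cols <- predictor_columns()
  unknown <- setdiff(predictors, names(cols))
  if (length(unknown))
    stop("configuration error: unknown predictors: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  df <- as.data.frame(cohort)[, c("wmh_followup", cols[predictors])]
  names(df) <- c("wmh_followup", predictors)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < length(predictors) + 2L)
    stop("insufficient data: need at least ", length(predictors) + 2L,
         " complete cases, have ", n, call. = FALSE)
  tidy_fit <- function(fit) {
    sm <- summary(fit)
    co <- sm$coefficients
    ci <- stats::confint(fit)
    keep <- setdiff(rownames(co), "(Intercept)")
    data.frame(predictor = keep,
               estimate = co[keep, 1],
               conf_low = ci[keep, 1],
               conf_high = ci[keep, 2],
               p_value = co[keep, 4],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  uni <- do.call(rbind, lapply(predictors, function(p) {
    fit <- stats::lm(stats::reformulate(p, "wmh_followup"), data = df)
    out <- tidy_fit(fit)
    out$r_squared <- summary(fit)$r.squared
    out
  }))
  multi_fit <- stats::lm(stats::reformulate(predictors, "wmh_followup"),
                         data = df)
  aliased <- summary(multi_fit)$aliased
  if (any(aliased[setdiff(names(aliased), "(Intercept)")]))
    stop("singularity error: collinear predictors: ",
         paste(names(aliased)[aliased], collapse = ", "), call. = FALSE)
  multi <- tidy_fit(multi_fit)
  structure(list(univariate = uni,
                 multivariable = multi,
                 r_squared = summary(multi_fit)$r.squared,
                 resid_sd = summary(multi_fit)$sigma,
                 n = n),
            class = "wmh_progression_fits")
}

#' @export
print.wmh_progression_fits <- function(x, digits = 3, ...) {
  cat(sprintf("Follow-up WMH volume regressions (n = %d complete cases)\n",
              x$n))
  cat(sprintf("Multivariable model: R-squared %.3f, residual SD %.2f ml\n\n",
              x$r_squared, x$resid_sd))
  tab <- merge(x$univariate[, c("predictor", "estimate", "p_value")],
               x$multivariable[, c("predictor", "estimate", "p_value")],
               by = "predictor", suffixes = c("_unadj", "_adj"), sort = FALSE)
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Variance inflation factors for the progression predictors
#'
#' `VIF_j = 1 / (1 - R^2_j)`, where `R^2_j` is from regressing predictor `j`
#' on the remaining predictors (complete cases). Perfectly collinear
#' predictors are reported as infinite, with a warning.
#'
#' @inheritParams fit_progression_models
#' @return Named numeric vector of VIFs (class `wmh_vif`).
#' @export
compute_vif <- function(cohort, predictors = progression_predictors()) {
  cols <- predictor_columns()
  in_cohort <- predictors %in% names(cols)
  use <- ifelse(in_cohort, cols[predictors], predictors)
  df <- as.data.frame(cohort)[, use, drop = FALSE]
  names(df) <- predictors
  df <- df[stats::complete.cases(df), , drop = FALSE]
  vifs <- vapply(predictors, function(p) {
    fit <- stats::lm(stats::reformulate(setdiff(predictors, p), p), data = df)
    # perfect fits (the infinite-VIF case) make summary() warn; handled below
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(is.infinite(vifs)))
    warning("perfect collinearity: infinite VIF for ",
            paste(names(vifs)[is.infinite(vifs)], collapse = ", "),
            call. = FALSE)
  structure(vifs, class = "wmh_vif", n = nrow(df))
}

#' @export
print.wmh_vif <- function(x, ...) {
  cat("Variance inflation factors (n =", attr(x, "n"), ")\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Ordinal logistic regression of Fazekas score on WMH volume
#'
#' Proportional-odds model of baseline Fazekas category on baseline WMH
#' volume, fitted by maximum likelihood ([MASS::polr()]); reports the odds
#' ratio per 1 ml with a Wald 95 percent confidence interval and the
#' estimated cutpoints.
#'
#' @param cohort A `wmh_cohort` or data frame with `fazekas_baseline` and
#'   `wmh_baseline`.
#' @return Object of class `wmh_ordinal_fit`: list with `odds_ratio`,
#'   `conf_low`, `conf_high`, `log_or`, `se`, `cutpoints`, `n`.
#' @export
fit_volume_to_fazekas <- function(cohort) {
  df <- as.data.frame(cohort)[, c("fazekas_baseline", "wmh_baseline")]
  df <- df[stats::complete.cases(df), ]
  if (length(unique(df$fazekas_baseline)) < 2L)
    stop("degenerate outcome: fewer than two Fazekas categories present",
         call. = FALSE)
  df$fazekas_baseline <- factor(df$fazekas_baseline, ordered = TRUE)
  if (nlevels(df$fazekas_baseline) == 2L) {
    # proportional odds with two categories is binary logistic regression;
    # long-tailed volumes can push fitted probabilities to 0/1 numerically
    fit <- suppressWarnings(
      stats::glm(fazekas_baseline ~ wmh_baseline, data = df,
                 family = stats::binomial()))
    beta <- stats::coef(fit)[["wmh_baseline"]]
    se <- sqrt(diag(stats::vcov(fit)))[["wmh_baseline"]]
    cuts <- -stats::coef(fit)[["(Intercept)"]]
  } else {
    # polr's internal start-value glm can warn about fitted 0/1 probabilities
    # on long-tailed volume data; harmless for the ML fit itself
    fit <- suppressWarnings(
      MASS::polr(fazekas_baseline ~ wmh_baseline, data = df, Hess = TRUE))
    beta <- stats::coef(fit)[["wmh_baseline"]]
    se <- sqrt(diag(stats::vcov(fit)))[["wmh_baseline"]]
    cuts <- fit$zeta
  }
  structure(list(odds_ratio = exp(beta),
                 conf_low = exp(beta - qnorm(0.975) * se),
                 conf_high = exp(beta + qnorm(0.975) * se),
                 log_or = beta, se = se,
                 cutpoints = cuts, n = nrow(df)),
            class = "wmh_ordinal_fit")
}

#' @export
print.wmh_ordinal_fit <- function(x, ...) {
  cat(sprintf("Proportional-odds fit: OR %.3f per ml (95%% CI %.3f-%.3f), n = %d\n",
              x$odds_ratio, x$conf_low, x$conf_high, x$n))
  invisible(x)
}

#' Compare completers with non-completers
#'
#' One comparison per baseline variable, completers minus non-completers (a
#' positive difference means completers are higher): Welch t-tests (or
#' pooled-variance, via `welch = FALSE`) for continuous variables,
#' chi-square tests for binary variables (difference in percentage points),
#' and one overall chi-square across the seven Fazekas categories.
#'
#' @param cohort A `wmh_cohort` with the `dropout` indicator set.
#' @param welch Use unequal-variance t-tests (default TRUE).
#' @param correct Apply continuity correction to chi-square tests (default
#'   FALSE).
#' @return Data frame of class `wmh_group_comparison`: variable, type,
#'   difference, CI bounds, p-value, test used.
#' @export
compare_dropout_groups <- function(cohort, welch = TRUE, correct = FALSE) {
  check_flag(welch, "welch"); check_flag(correct, "correct")
  df <- as.data.frame(cohort)
  g <- df$dropout == 0L  # completers
  if (!any(g) || all(g))
    stop("insufficient data: both completer and non-completer groups must be ",
         "non-empty", call. = FALSE)
  cont <- c(wmh_baseline = "Baseline WMH volume (ml)", age = "Age (years)",
            map = "MAP (mmHg)", pp = "PP (mmHg)")
  bin <- c(hypertension = "Hypertension", subtype = "Stroke subtype lacunar",
           smoker = "Smoker", diabetes = "Diabetes",
           hyperlipidaemia = "Hyperlipidaemia")
  rows <- list()
  for (v in names(cont)) {
    diff_v <- mean(df[[v]][g]) - mean(df[[v]][!g])
    tt <- tryCatch(stats::t.test(df[[v]][g], df[[v]][!g], var.equal = !welch),
                   error = function(e) NULL)  # essentially-constant data
    rows[[v]] <- data.frame(variable = cont[[v]], type = "continuous",
                            difference = diff_v,
                            conf_low = if (is.null(tt)) diff_v else tt$conf.int[1],
                            conf_high = if (is.null(tt)) diff_v else tt$conf.int[2],
                            p_value = if (is.null(tt))
                              (if (diff_v == 0) 1 else NA_real_) else tt$p.value,
                            test = if (welch) "Welch t" else "pooled t")
  }
  for (v in names(bin)) {
    tab <- rbind(completers = c(sum(df[[v]][g] == 1), sum(df[[v]][g] == 0)),
                 dropouts = c(sum(df[[v]][!g] == 1), sum(df[[v]][!g] == 0)))
    pt <- suppressWarnings(stats::prop.test(tab, correct = correct))
    rows[[v]] <- data.frame(variable = bin[[v]], type = "binary",
                            difference = 100 * unname(diff(rev(pt$estimate))),
                            conf_low = 100 * pt$conf.int[1],
                            conf_high = 100 * pt$conf.int[2],
                            p_value = pt$p.value,
                            test = "chi-square")
  }
  faz_tab <- table(factor(df$fazekas_baseline, levels = 0:6), !g)
  faz_p <- suppressWarnings(stats::chisq.test(faz_tab, correct = correct))$p.value
  rows[["fazekas"]] <- data.frame(variable = "Fazekas score (0-6)",
                                  type = "ordinal",
                                  difference = mean(df$fazekas_baseline[g]) -
                                    mean(df$fazekas_baseline[!g]),
                                  conf_low = NA_real_, conf_high = NA_real_,
                                  p_value = faz_p,
                                  test = "chi-square (7 categories)")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("wmh_group_comparison", "data.frame")
  out
}

#' @export
print.wmh_group_comparison <- function(x, digits = 3, ...) {
  cat("Completers minus non-completers (positive = completers higher)\n")
  print(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write tidy analysis results as CSV
#'
#' @param x A `wmh_progression_fits` or `wmh_group_comparison`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_analysis_csv <- function(x, path) {
  df <- if (inherits(x, "wmh_progression_fits")) {
    uni <- x$univariate; uni$model <- "univariate"
    mult <- x$multivariable; mult$model <- "multivariable"
    mult$r_squared <- x$r_squared
    rbind(uni, mult)
  } else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
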