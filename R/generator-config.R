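#' Names of the ten progression-model predictors
#'
#' The hypothesis-driven predictor set used throughout: baseline WMH volume
#' (ml), total Fazekas score, mean arterial pressure (mmHg), pulse pressure
#' (mmHg), hypertension, age (years), stroke subtype (lacunar = 1), smoking,
#' diabetes and hyperlipidaemia.
#'
#' @return Character vector of length ten.
#' @export
progression_predictors <- function() {
  c("baseline_volume", "fazekas", "map", "pp", "hypertension",
    "age", "subtype", "smoking", "diabetes", "hyperlipidaemia")
}

# default adjusted regression coefficients of the follow-up-volume model
# (ml of 1-year follow-up WMH volume per unit of predictor)
default_prog_coefs <- function() {
  c(baseline_volume = 0.73, fazekas = 2.93, map = -0.10, pp = 0.03,
    hypertension = -1.40, age = -0.02, subtype = -0.85, smoking = 0.17,
    diabetes = -1.98, hyperlipidaemia = -1.10)
}

# map predictor names onto cohort-table column names
predictor_columns <- function() {
  c(baseline_volume = "wmh_baseline", fazekas = "fazekas_baseline",
    map = "map", pp = "pp", hypertension = "hypertension", age = "age",
    subtype = "subtype", smoking = "smoker", diabetes = "diabetes",
    hyperlipidaemia = "hyperlipidaemia")
}

#' Synthetic-cohort generator configuration
#'
#' Bundles every parameter of the synthetic mild-stroke cohort generator:
#' the lognormal baseline WMH-volume law, the latent ordered-logit link from
#' volume to Fazekas score, the linear follow-up-volume model, covariate
#' marginals, and the logistic informative-dropout model. Calibrated
#' quantities (Fazekas cutpoints, progression intercept, residual SD,
#' dropout intercept) are normally derived by [default_generator_config()]
#' rather than supplied by hand.
#'
#' @param n_patients Cohort size (the study cohort had 264).
#' @param seed Integer seed for the pseudo-random stream.
#' @param vol_log_mean,vol_log_sd Mean and SD of log baseline WMH volume (ml
#'   on the log scale).
#' @param faz_slope Log-odds increase in Fazekas category per ml of baseline
#'   volume; `log(1.21)` by default.
#' @param faz_cutpoints Six strictly increasing cutpoints of the latent
#'   ordinal model mapping volume to Fazekas 0--6.
#' @param prog_coefs Named coefficient vector over
#'   [progression_predictors()], in ml of follow-up volume per predictor unit.
#' @param prog_intercept Intercept of the follow-up-volume model (ml).
#' @param resid_sd Residual SD of the follow-up-volume model (ml), > 0.
#' @param age_mean,age_sd Age marginal (years).
#' @param map_mean,map_sd Mean arterial pressure marginal (mmHg).
#' @param pp_mean,pp_sd Pulse pressure marginal (mmHg).
#' @param map_pp_corr Correlation between MAP and PP.
#' @param prev_hypertension,prev_lacunar,prev_smoker,prev_diabetes,prev_hyperlipidaemia
#'   Covariate prevalences in `[0, 1]`.
#' @param dropout_intercept,dropout_age_coef,dropout_faz_coef Log-odds
#'   parameters of the logistic missingness model in age and baseline
#'   Fazekas score.
#' @return A validated object of class `wmh_generator_config`.
#' @seealso [default_generator_config()] for the calibrated defaults,
#'   [generate_cohort()] for use.
#' @export
generator_config <- function(n_patients = 264L,
                             seed = 1L,
                             vol_log_mean,
                             vol_log_sd,
                             faz_slope = log(1.21),
                             faz_cutpoints,
                             prog_coefs = default_prog_coefs(),
                             prog_intercept,
                             resid_sd,
                             age_mean = 65.3, age_sd = 11.3,
                             map_mean = 102.8, map_sd = 15.4,
                             pp_mean = 63, pp_sd = 20.7,
                             map_pp_corr = 0.3,
                             prev_hypertension = 0.747,
                             prev_lacunar = 0.458,
                             prev_smoker = 0.384,
                             prev_diabetes = 0.111,
                             prev_hyperlipidaemia = 0.611,
                             dropout_intercept,
                             dropout_age_coef,
                             dropout_faz_coef) {
  cfg <- list(
    n_patients = n_patients, seed = as.integer(seed),
    vol_log_mean = vol_log_mean, vol_log_sd = vol_log_sd,
    faz_slope = faz_slope, faz_cutpoints = faz_cutpoints,
    prog_coefs = prog_coefs, prog_intercept = prog_intercept,
    resid_sd = resid_sd,
    age_mean = age_mean, age_sd = age_sd,
    map_mean = map_mean, map_sd = map_sd,
    pp_mean = pp_mean, pp_sd = pp_sd, map_pp_corr = map_pp_corr,
    prev_hypertension = prev_hypertension, prev_lacunar = prev_lacunar,
    prev_smoker = prev_smoker, prev_diabetes = prev_diabetes,
    prev_hyperlipidaemia = prev_hyperlipidaemia,
    dropout_intercept = dropout_intercept,
    dropout_age_coef = dropout_age_coef,
    dropout_faz_coef = dropout_faz_coef)
  class(cfg) <- "wmh_generator_config"
  validate_generator_config(cfg)
}

#' Validate a generator configuration
#'
#' Checks every invariant of the configuration (positive SDs, prevalences in
#' `[0, 1]`, strictly increasing cutpoints, the exact ten-predictor
#' coefficient vector) and fails naming the offending field.
#'
#' @param config A `wmh_generator_config`.
#' @return The config, invisibly usable, if valid.
#' @export
validate_generator_config <- function(config) {
  if (!inherits(config, "wmh_generator_config"))
    stop("configuration error: not a `wmh_generator_config`", call. = FALSE)
  with(config, {
    if (!is.numeric(n_patients) || length(n_patients) != 1L ||
        n_patients < 0 || n_patients != floor(n_patients))
      stop("configuration error: `n_patients` must be a nonnegative integer",
           call. = FALSE)
    check_number(seed, "seed")
    check_number(vol_log_sd, "vol_log_sd", lower = 0, open_lower = TRUE)
    check_number(vol_log_mean, "vol_log_mean")
    check_number(faz_slope, "faz_slope")
    if (!is.numeric(faz_cutpoints) || length(faz_cutpoints) != 6L ||
        any(!is.finite(faz_cutpoints)) || any(diff(faz_cutpoints) <= 0))
      stop("configuration error: `faz_cutpoints` must be 6 strictly ",
           "increasing finite values", call. = FALSE)
    if (!setequal(names(prog_coefs), progression_predictors()) ||
        length(prog_coefs) != 10L)
      stop("configuration error: `prog_coefs` must be named by exactly the ",
           "ten predictors: ",
           paste(progression_predictors(), collapse = ", "), call. = FALSE)
    check_number(prog_intercept, "prog_intercept")
    check_number(resid_sd, "resid_sd", lower = 0, open_lower = TRUE)
    for (f in c("age_sd", "map_sd", "pp_sd"))
      check_number(config[[f]], f, lower = 0, open_lower = TRUE)
    check_number(map_pp_corr, "map_pp_corr", lower = -1, upper = 1)
    for (f in c("prev_hypertension", "prev_lacunar", "prev_smoker",
                "prev_diabetes", "prev_hyperlipidaemia"))
      check_number(config[[f]], f, lower = 0, upper = 1)
    check_number(dropout_intercept, "dropout_intercept")
    check_number(dropout_age_coef, "dropout_age_coef")
    check_number(dropout_faz_coef, "dropout_faz_coef")
  })
  config
}

#' @export
print.wmh_generator_config <- function(x, ...) {
  cat("Synthetic mild-stroke cohort generator configuration\n")
  cat(sprintf("  n_patients: %d, seed: %d\n", x$n_patients, x$seed))
  vm <- exp(x$vol_log_mean + x$vol_log_sd^2 / 2)
  vs <- vm * sqrt(expm1(x$vol_log_sd^2))
  cat(sprintf("  baseline WMH volume: lognormal, mean %.1f ml, SD %.1f ml\n",
              vm, vs))
  cat(sprintf("  Fazekas link: OR %.3f per ml, cutpoints %s\n",
              exp(x$faz_slope),
              paste(sprintf("%.2f", x$faz_cutpoints), collapse = " ")))
  cat(sprintf("  progression model: intercept %.2f ml, residual SD %.2f ml\n",
              x$prog_intercept, x$resid_sd))
  cat(sprintf("  dropout model: logit p = %.2f + %.4f age + %.3f fazekas\n",
              x$dropout_intercept, x$dropout_age_coef, x$dropout_faz_coef))
  invisible(x)
}

#' Calibrate latent ordinal cutpoints to target category proportions
#'
#' Back-solves the six cutpoints of the ordered-logit model
#' `P(Fazekas <= k | v) = plogis(c_k - faz_slope * v)` so that the marginal
#' category probabilities under the lognormal baseline-volume law match the
#' target proportions. Each cutpoint solves one monotone equation
#' `E_v[plogis(c_k - faz_slope v)] = cumulative target`, by root-finding on
#' a numerically integrated expectation (tolerance 1e-8 of the integral).
#'
#' @param vol_params Named vector or list with `meanlog` and `sdlog` of the
#'   baseline-volume lognormal.
#' @param faz_slope Log-odds per ml.
#' @param target_proportions Seven positive category masses (renormalised).
#' @return Strictly increasing numeric vector of `K - 1` cutpoints.
#' @examples
#' calibrate_cutpoints(c(meanlog = 2.681, sdlog = 0.906), log(1.21),
#'                     c(4.2, 9.0, 36.8, 12.6, 15.3, 9.0, 13.2))
#' @export
calibrate_cutpoints <- function(vol_params, faz_slope, target_proportions) {
  meanlog <- vol_params[["meanlog"]]; sdlog <- vol_params[["sdlog"]]
  check_number(meanlog, "meanlog"); check_number(sdlog, "sdlog", lower = 0,
                                                open_lower = TRUE)
  if (any(target_proportions <= 0))
    stop("calibration failure: all target proportions must be positive",
         call. = FALSE)
  p <- target_proportions / sum(target_proportions)
  cum <- cumsum(p)[-length(p)]
  if (any(diff(cum) <= 0))
    stop("calibration failure: cumulative targets are not strictly increasing",
         call. = FALSE)
  cuts <- vapply(cum, function(target) {
    f <- function(cc) lnorm_expect(function(v) plogis(cc - faz_slope * v),
                                   meanlog, sdlog) - target
    uniroot(f, lower = -500, upper = 500, tol = 1e-8,
            extendInt = "upX")$root
  }, numeric(1))
  if (any(diff(cuts) <= 0))
    stop("calibration failure: solved cutpoints are not strictly increasing",
         call. = FALSE)
  cuts
}

# category probabilities P(F = k | v) under the ordered-logit link;
# returns a length(v) x K matrix
ordinal_category_probs <- function(v, cutpoints, slope) {
  cp <- vapply(cutpoints, function(cc) plogis(cc - slope * v),
               numeric(length(v)))
  cp <- matrix(cp, nrow = length(v))
  cbind(cp[, 1, drop = FALSE], cp[, -1, drop = FALSE] -
          cp[, -ncol(cp), drop = FALSE], 1 - cp[, ncol(cp), drop = FALSE])
}

# moments of (V, F) and of the full linear predictor under the generator law
generator_moments <- function(meanlog, sdlog, cutpoints, slope, prog_coefs,
                              covariate_means, covariate_vars, map_pp_cov) {
  k <- seq_len(length(cutpoints) + 1L) - 1L
  Ev <- exp(meanlog + sdlog^2 / 2)
  Vv <- Ev^2 * expm1(sdlog^2)
  EF1v <- function(v) drop(ordinal_category_probs(v, cutpoints, slope) %*% k)
  EF2v <- function(v) drop(ordinal_category_probs(v, cutpoints, slope) %*% k^2)
  EF <- lnorm_expect(EF1v, meanlog, sdlog)
  EF2 <- lnorm_expect(EF2v, meanlog, sdlog)
  EvF <- lnorm_expect(function(v) v * EF1v(v), meanlog, sdlog)
  varF <- EF2 - EF^2
  covVF <- EvF - Ev * EF
  bv <- prog_coefs[["baseline_volume"]]; bF <- prog_coefs[["fazekas"]]
  other <- setdiff(progression_predictors(), c("baseline_volume", "fazekas"))
  var_others <- sum(prog_coefs[other]^2 * covariate_vars[other]) +
    2 * prog_coefs[["map"]] * prog_coefs[["pp"]] * map_pp_cov
  var_vf <- bv^2 * Vv + bF^2 * varF + 2 * bv * bF * covVF
  list(Ev = Ev, Vv = Vv, EF = EF, varF = varF, covVF = covVF,
       mu_others = sum(prog_coefs[other] * covariate_means[other]),
       var_others = var_others, var_vf = var_vf,
       var_lp = var_vf + var_others)
}

#' Calibrated default generator configuration
#'
#' Builds the generator configuration calibrated so that large generated
#' cohorts reproduce the study cohort's statistical structure: baseline WMH
#' volume mean 22.0 / SD 24.8 ml (lognormal, moment-matched), Fazekas
#' marginals 4.2/9.0/36.8/12.6/15.3/9.0/13.2 percent via ordered-logit
#' cutpoints, mean 1-year progression 1.27 ml, multivariable R-squared 0.90
#' (which fixes the residual SD), 28 percent informative dropout, and
#' completers younger than non-completers by 5.7 years. All calibrations are
#' deterministic root-finds on numerically integrated expectations, solved
#' at call time, never hard-coded.
#'
#' @param n_patients Cohort size (default 264, the study cohort).
#' @param seed Integer seed.
#' @param mean_progression Target mean 1-year WMH volume change (ml).
#' @param r_squared Target multivariable R-squared of the follow-up model.
#' @param dropout_rate Target overall dropout fraction.
#' @param age_gap Target mean age difference, completers minus
#'   non-completers (years; negative because completers are younger).
#' @param fazekas_gap Target mean baseline-Fazekas difference, completers
#'   minus non-completers (derived from the per-category differences of the
#'   cohort's completer/non-completer comparison).
#' @return A calibrated `wmh_generator_config`.
#' @examples
#' cfg <- default_generator_config(n_patients = 500, seed = 42)
#' cohort <- simulate_study(cfg)
#' @export
default_generator_config <- function(n_patients = 264L, seed = 1L,
                                     mean_progression = 1.27,
                                     r_squared = 0.90,
                                     dropout_rate = 0.28,
                                     age_gap = -5.7,
                                     fazekas_gap = -0.515) {
  # lognormal matched to mean 22.0 / SD 24.8 ml
  mean_v <- 22.0; sd_v <- 24.8
  s2 <- log(1 + (sd_v / mean_v)^2)
  meanlog <- log(mean_v) - s2 / 2
  sdlog <- sqrt(s2)
  slope <- log(1.21)
  cuts <- calibrate_cutpoints(c(meanlog = meanlog, sdlog = sdlog), slope,
                              unclass(fazekas_distribution()))
  coefs <- default_prog_coefs()
  cov_means <- c(map = 102.8, pp = 63, hypertension = 0.747, age = 65.3,
                 subtype = 0.458, smoking = 0.384, diabetes = 0.111,
                 hyperlipidaemia = 0.611)
  cov_vars <- c(map = 15.4^2, pp = 20.7^2,
                hypertension = 0.747 * 0.253, age = 11.3^2,
                subtype = 0.458 * 0.542, smoking = 0.384 * 0.616,
                diabetes = 0.111 * 0.889, hyperlipidaemia = 0.611 * 0.389)
  map_pp_cov <- 0.3 * 15.4 * 20.7
  mom <- generator_moments(meanlog, sdlog, cuts, slope, coefs,
                           cov_means, cov_vars, map_pp_cov)
  # residual SD from the R^2 target: resid^2 = var(lp) (1 - R^2) / R^2
  resid_sd <- sqrt(mom$var_lp * (1 - r_squared) / r_squared)
  # intercept from the mean-progression target, accounting for the
  # nonnegativity truncation of follow-up volumes; the non-(volume, Fazekas)
  # covariate spread is folded into an effective noise SD
  sig_eff <- sqrt(resid_sd^2 + mom$var_others)
  k <- 0:6
  expected_followup <- function(a) {
    lnorm_expect(function(v) {
      pk <- ordinal_category_probs(v, cuts, slope)
      lp <- a + coefs[["baseline_volume"]] * v + mom$mu_others
      tm <- outer(lp, coefs[["fazekas"]] * k, "+")
      rowSums(pk * truncnorm_mean(tm, sig_eff))
    }, meanlog, sdlog)
  }
  intercept <- uniroot(function(a) expected_followup(a) -
                         (mean_v + mean_progression),
                       lower = -100, upper = 100, tol = 1e-8)$root
  drop_par <- calibrate_dropout(dropout_rate, age_gap, fazekas_gap,
                                age_mean = 65.3, age_sd = 11.3,
                                faz_marginal = marginal_fazekas(meanlog, sdlog,
                                                                cuts, slope))
  generator_config(n_patients = n_patients, seed = seed,
                   vol_log_mean = meanlog, vol_log_sd = sdlog,
                   faz_slope = slope, faz_cutpoints = cuts,
                   prog_coefs = coefs, prog_intercept = intercept,
                   resid_sd = resid_sd,
                   dropout_intercept = drop_par[["intercept"]],
                   dropout_age_coef = drop_par[["age_coef"]],
                   dropout_faz_coef = drop_par[["faz_coef"]])
}

#' Predicted large-sample moments of a generator configuration
#'
#' Deterministic quadrature predictions of what an infinitely large cohort
#' from this configuration would show: baseline volume mean/SD, Fazekas
#' marginals, follow-up volume mean and SD (after the nonnegativity
#' truncation, whose variance shrinkage is accounted for), mean 1-year
#' progression, and the dropout rate. Used to verify generated cohorts
#' against the calibration itself.
#'
#' @param config A [generator_config()].
#' @return List: `baseline_mean`, `baseline_sd`, `fazekas_marginal`,
#'   `followup_mean`, `followup_sd`, `mean_progression`, `dropout_rate`.
#' @export
generator_predictions <- function(config) {
  validate_generator_config(config)
  meanlog <- config$vol_log_mean; sdlog <- config$vol_log_sd
  cuts <- config$faz_cutpoints; slope <- config$faz_slope
  coefs <- config$prog_coefs
  cov_means <- c(map = config$map_mean, pp = config$pp_mean,
                 hypertension = config$prev_hypertension,
                 age = config$age_mean, subtype = config$prev_lacunar,
                 smoking = config$prev_smoker, diabetes = config$prev_diabetes,
                 hyperlipidaemia = config$prev_hyperlipidaemia)
  cov_vars <- c(map = config$map_sd^2, pp = config$pp_sd^2,
                hypertension = config$prev_hypertension *
                  (1 - config$prev_hypertension),
                age = config$age_sd^2,
                subtype = config$prev_lacunar * (1 - config$prev_lacunar),
                smoking = config$prev_smoker * (1 - config$prev_smoker),
                diabetes = config$prev_diabetes * (1 - config$prev_diabetes),
                hyperlipidaemia = config$prev_hyperlipidaemia *
                  (1 - config$prev_hyperlipidaemia))
  mom <- generator_moments(meanlog, sdlog, cuts, slope, coefs, cov_means,
                           cov_vars,
                           config$map_pp_corr * config$map_sd * config$pp_sd)
  sig_eff <- sqrt(config$resid_sd^2 + mom$var_others)
  k <- seq_len(length(cuts) + 1L) - 1L
  # truncated-at-zero normal moments: z = mu/sigma, h = phi(z)/Phi(z)
  cell_moments <- function(fn) {
    lnorm_expect(function(v) {
      pk <- ordinal_category_probs(v, cuts, slope)
      lp <- config$prog_intercept + coefs[["baseline_volume"]] * v +
        mom$mu_others
      mu <- outer(lp, coefs[["fazekas"]] * k, "+")
      rowSums(pk * fn(mu))
    }, meanlog, sdlog)
  }
  m1 <- cell_moments(function(mu) truncnorm_mean(mu, sig_eff))
  m2 <- cell_moments(function(mu) {
    z <- mu / sig_eff
    h <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
    v <- sig_eff^2 * (1 - h^2 - z * h)
    v + (mu + sig_eff * h)^2
  })
  marg <- marginal_fazekas(meanlog, sdlog, cuts, slope)
  # dropout rate over the independent (age, Fazekas) joint
  grid <- qnorm((seq_len(2000L) - 0.5) / 2000L, config$age_mean, config$age_sd)
  drate <- sum(vapply(k, function(kk)
    marg[kk + 1L] * mean(plogis(config$dropout_intercept +
                                  config$dropout_age_coef * grid +
                                  config$dropout_faz_coef * kk)),
    numeric(1)))
  list(baseline_mean = mom$Ev, baseline_sd = sqrt(mom$Vv),
       fazekas_marginal = marg,
       followup_mean = m1, followup_sd = sqrt(m2 - m1^2),
       mean_progression = m1 - mom$Ev,
       dropout_rate = drate)
}

marginal_fazekas <- function(meanlog, sdlog, cutpoints, slope) {
  vapply(seq_len(length(cutpoints) + 1L), function(j)
    lnorm_expect(function(v) ordinal_category_probs(v, cutpoints, slope)[, j],
                 meanlog, sdlog), numeric(1))
}

# solve the three dropout-model parameters for three targets: overall rate,
# completers-minus-dropouts age gap, and Fazekas gap.  Age and Fazekas are
# independent under the generator, so Gauss-Seidel on 1-D roots converges in
# a few sweeps; expectations use a midpoint quantile grid over age.
calibrate_dropout <- function(rate, age_gap, faz_gap, age_mean, age_sd,
                              faz_marginal, grid_size = 2000L) {
  ages <- qnorm((seq_len(grid_size) - 0.5) / grid_size, age_mean, age_sd)
  k <- seq_along(faz_marginal) - 1L
  EF <- sum(faz_marginal * k)
  stats_for <- function(a0, ba, bf) {
    # P matrix: grid x category
    p <- vapply(k, function(kk) plogis(a0 + ba * ages + bf * kk),
                numeric(grid_size))
    w <- rep(faz_marginal, each = grid_size) / grid_size
    pbar <- sum(p * w)
    e_age_d <- sum(ages * p * w) / pbar
    e_age_c <- (age_mean - pbar * e_age_d) / (1 - pbar)
    e_faz_d <- sum(rep(k, each = grid_size) * p * w) / pbar
    e_faz_c <- (EF - pbar * e_faz_d) / (1 - pbar)
    c(rate = pbar, age_gap = e_age_c - e_age_d, faz_gap = e_faz_c - e_faz_d)
  }
  a0 <- qlogis(rate); ba <- -age_gap / age_sd^2; bf <- -faz_gap / 2.8
  for (i in 1:25) {
    a0 <- uniroot(function(x) stats_for(x, ba, bf)["rate"] - rate,
                  lower = a0 - 8, upper = a0 + 8, tol = 1e-10)$root
    ba <- uniroot(function(x) stats_for(a0, x, bf)["age_gap"] - age_gap,
                  lower = -1, upper = 1, tol = 1e-10)$root
    bf <- uniroot(function(x) stats_for(a0, ba, x)["faz_gap"] - faz_gap,
                  lower = -3, upper = 3, tol = 1e-10)$root
    got <- stats_for(a0, ba, bf)
    if (max(abs(got - c(rate, age_gap, faz_gap))) < 1e-7) break
  }
  c(intercept = a0, age_coef = ba, faz_coef = bf)
}
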