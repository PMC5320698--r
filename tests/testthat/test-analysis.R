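# build a minimal cohort-shaped data frame from explicit columns
mini_cohort <- function(...) {
  df <- data.frame(...)
  defaults <- list(age = 65, map = 100, pp = 60, hypertension = 0L,
                   diabetes = 0L, smoker = 0L, hyperlipidaemia = 0L,
                   subtype = 0L, fazekas_baseline = 2L, wmh_baseline = 10,
                   wmh_followup = 11, dropout = 0L)
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  df
}

test_that("ordinary least squares fits agree with hand-worked cases", {
  # three-point line y = 2x through the origin
  co <- mini_cohort(wmh_baseline = c(0, 1, 2), wmh_followup = c(0, 2, 4))
  fit <- suppressWarnings(  # perfect fit: summary() warns
    fit_progression_models(co, predictors = "baseline_volume"))
  expect_equal(fit$univariate$estimate, 2.0, tolerance = 1e-12)
  expect_equal(fit$univariate$r_squared, 1.0, tolerance = 1e-12)

  # outcome identically equal to the predictor
  co <- mini_cohort(wmh_baseline = c(3, 1, 4, 1, 5, 9.2))
  co$wmh_followup <- co$wmh_baseline
  fit <- suppressWarnings(
    fit_progression_models(co, predictors = "baseline_volume"))
  expect_equal(fit$univariate$estimate, 1.0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)

  expect_error(fit_progression_models(co, predictors = "cholesterol"),
               "unknown predictors")
  expect_error(fit_progression_models(co[1:2, ], "baseline_volume"),
               "insufficient data")
})

test_that("multivariable fit recovers generator coefficients on synthetic data", {
  # truncation-free regime (large intercept keeps every linear predictor
  # far from zero): OLS must recover every coefficient
  cfg <- with_n(default_cfg, 40000, seed = 8)
  free <- cfg
  free$prog_intercept <- cfg$prog_intercept + 60
  co_free <- simulate_followup(generate_cohort(free), free)
  fit_free <- fit_progression_models(co_free)
  est <- setNames(fit_free$multivariable$estimate,
                  fit_free$multivariable$predictor)
  truth <- free$prog_coefs[names(est)]
  half_ci <- (fit_free$multivariable$conf_high -
                fit_free$multivariable$conf_low) / 2
  expect_true(all(abs(est - truth) < 2 * half_ci))

  # default regime: the nonnegativity truncation attenuates coefficients
  # toward zero but leaves the baseline-volume coefficient on target
  co <- simulate_followup(generate_cohort(cfg), cfg)
  fit <- fit_progression_models(co)
  est_d <- setNames(fit$multivariable$estimate, fit$multivariable$predictor)
  truth_d <- cfg$prog_coefs[names(est_d)]
  expect_lt(abs(est_d[["baseline_volume"]] - 0.73), 0.04)
  big <- abs(truth_d) > 0.5  # attenuation visible above the noise
  expect_true(all(abs(est_d[big]) < abs(truth_d[big]) + 0.05))
  expect_identical(fit$n, nrow(co))

  # complete cases only: blanking rows drops them from n
  co2 <- co
  co2$wmh_followup[1:500] <- NA
  expect_identical(fit_progression_models(co2)$n, nrow(co) - 500L)
})

test_that("volume rescaling rescales coefficients and leaves fit statistics alone", {
  cfg <- with_n(default_cfg, 4000, seed = 12)
  co <- simulate_followup(generate_cohort(cfg), cfg)
  scaled <- co
  scaled$wmh_baseline <- co$wmh_baseline / 10
  f1 <- fit_progression_models(co)
  f2 <- fit_progression_models(scaled)
  i <- which(f1$multivariable$predictor == "baseline_volume")
  expect_equal(f2$multivariable$estimate[i], 10 * f1$multivariable$estimate[i],
               tolerance = 1e-9)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
  expect_equal(f2$multivariable$p_value, f1$multivariable$p_value,
               tolerance = 1e-9)
  expect_equal(unclass(compute_vif(scaled)), unclass(compute_vif(co)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("variance inflation factors match the closed form 1/(1 - R^2)", {
  # orthogonal design: VIF exactly 1
  gr <- expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1))
  gr$y <- rnorm(8)
  names(gr) <- c("map", "pp", "age", "wmh_followup")
  v <- compute_vif(gr, c("map", "pp", "age"))
  expect_equal(unclass(v), c(map = 1, pp = 1, age = 1), tolerance = 1e-12,
               ignore_attr = TRUE)

  # exact sample correlation 0.8 by construction: VIF = 1/(1 - 0.64)
  n <- 40
  z1 <- scale(rnorm(n)); z2 <- residuals(lm(rnorm(n) ~ z1))
  x1 <- drop(z1); x2 <- 0.8 * x1 / sd(x1) + sqrt(1 - 0.64) * z2 / sd(z2)
  df <- data.frame(map = x1, pp = x2, wmh_followup = rnorm(n))
  v2 <- compute_vif(df, c("map", "pp"))
  expect_equal(unname(unclass(v2)), rep(1 / (1 - cor(x1, x2)^2), 2),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(unclass(v2))[1], 1 / (1 - 0.64), tolerance = 1e-6)

  # duplicated predictor: infinite VIF, with a warning
  df$age <- df$map
  expect_warning(v3 <- compute_vif(df, c("map", "age")), "collinearity")
  expect_true(all(is.infinite(unclass(v3))))
})

test_that("VIFs agree with the car package on generated data", {
  cfg <- with_n(default_cfg, 3000, seed = 4)
  co <- simulate_followup(generate_cohort(cfg), cfg)
  mine <- compute_vif(co)
  cols <- c(wmh_followup = "wmh_followup", baseline_volume = "wmh_baseline",
            fazekas = "fazekas_baseline", map = "map", pp = "pp",
            hypertension = "hypertension", age = "age", subtype = "subtype",
            smoking = "smoker", diabetes = "diabetes",
            hyperlipidaemia = "hyperlipidaemia")
  df <- as.data.frame(co)[, cols]
  names(df) <- names(cols)
  ref <- car::vif(lm(wmh_followup ~ ., data = df))
  expect_equal(unclass(mine)[names(ref)], ref, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("proportional-odds fit reduces to binary logistic with two categories", {
  set.seed(71)
  v <- rlnorm(3000, 2.7, 0.9)
  faz <- rbinom(3000, 1, plogis(0.15 * v - 2)) + 2L
  co <- mini_cohort(wmh_baseline = v, fazekas_baseline = faz)
  fit <- fit_volume_to_fazekas(co)
  ref <- suppressWarnings(glm(I(faz == 3) ~ v, family = binomial))
  expect_equal(fit$log_or, unname(coef(ref)["v"]), tolerance = 1e-4)
  expect_true(fit$conf_low < fit$odds_ratio & fit$odds_ratio < fit$conf_high)

  co$fazekas_baseline <- 2L
  expect_error(fit_volume_to_fazekas(co), "degenerate outcome")
})

test_that("null proportional-odds slope is recovered as OR close to 1", {
  cfg <- with_n(default_cfg, 20000, seed = 14)
  cfg$faz_slope <- 0
  cfg$faz_cutpoints <- qlogis(cumsum(
    table1_fazekas_pct / sum(table1_fazekas_pct))[-7])
  co <- generate_cohort(cfg)
  fit <- fit_volume_to_fazekas(co)
  expect_equal(fit$odds_ratio, 1.0, tolerance = 0.01)
})

test_that("completer comparisons behave on identical and hand-made groups", {
  cfg <- with_n(default_cfg, 300, seed = 6)
  co <- simulate_followup(generate_cohort(cfg), cfg)
  # duplicate the cohort into both arms: all differences 0, t-test p = 1
  both <- rbind(co, co)
  both$dropout <- rep(c(0L, 1L), each = nrow(co))
  cmp <- compare_dropout_groups(both)
  cont <- cmp[cmp$type == "continuous", ]
  expect_equal(cont$difference, rep(0, nrow(cont)), tolerance = 1e-12)
  expect_equal(cont$p_value, rep(1, nrow(cont)), tolerance = 1e-12)
  expect_true(all(cmp$conf_low <= cmp$difference + 1e-9 |
                    is.na(cmp$conf_low)))

  # 2x2 table (20,10;10,20): uncorrected chi-square statistic 6.667
  co2 <- mini_cohort(hypertension = rep(c(1L, 0L, 1L, 0L), c(20, 10, 10, 20)))
  co2$dropout <- rep(c(0L, 1L), each = 30)
  cmp2 <- compare_dropout_groups(co2, correct = FALSE)
  row <- cmp2[cmp2$variable == "Hypertension", ]
  expect_equal(row$p_value, pchisq(20 / 3, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(row$difference, 100 * (20 / 30 - 10 / 30), tolerance = 1e-9)

  expect_error(compare_dropout_groups(co), "non-empty")
})

test_that("informative dropout leaves completers younger with lower Fazekas", {
  cfg <- with_n(default_cfg, 30000, seed = 16)
  co <- simulate_study(cfg)
  cmp <- compare_dropout_groups(co)
  age_diff <- cmp$difference[cmp$variable == "Age (years)"]
  expect_lt(abs(age_diff - (-5.7)), 0.7)
  faz_diff <- cmp$difference[cmp$variable == "Fazekas score (0-6)"]
  expect_lt(abs(faz_diff - (-0.515)), 0.12)
})
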