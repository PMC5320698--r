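test_that("configuration invariants are enforced and name the offending field", {
  expect_error(with_n(default_cfg, -1) |> validate_generator_config(),
               "n_patients")
  bad <- default_cfg; bad$resid_sd <- 0
  expect_error(validate_generator_config(bad), "resid_sd")
  bad <- default_cfg; bad$faz_cutpoints <- rev(bad$faz_cutpoints)
  expect_error(validate_generator_config(bad), "faz_cutpoints")
  bad <- default_cfg
  names(bad$prog_coefs)[1] <- "volume"
  expect_error(validate_generator_config(bad), "prog_coefs")
  bad <- default_cfg; bad$prev_diabetes <- 1.2
  expect_error(validate_generator_config(bad), "prev_diabetes")
})

test_that("cutpoint calibration matches its defining integrals", {
  vp <- c(meanlog = default_cfg$vol_log_mean, sdlog = default_cfg$vol_log_sd)

  # zero slope: cutpoints are exactly the logit quantiles of the cumulative
  # target proportions
  p <- table1_fazekas_pct / sum(table1_fazekas_pct)
  cuts0 <- calibrate_cutpoints(vp, 0, table1_fazekas_pct)
  expect_equal(cuts0, qlogis(cumsum(p)[-7]), tolerance = 1e-7)

  # study targets: six finite, strictly increasing cutpoints whose
  # integrated cumulative probabilities reproduce the targets
  cuts <- calibrate_cutpoints(vp, log(1.21), table1_fazekas_pct)
  expect_length(cuts, 6L)
  expect_true(all(is.finite(cuts)) && all(diff(cuts) > 0))
  for (k in 1:6) {
    got <- integrate(function(v)
      plogis(cuts[k] - log(1.21) * v) * dlnorm(v, vp["meanlog"], vp["sdlog"]),
      0, Inf, rel.tol = 1e-10)$value
    expect_equal(got, cumsum(p)[k], tolerance = 1e-6)
  }

  # permuting the targets changes cumulative sums, and the solved cutpoints
  # are the independent roots of those sums
  perm <- c(3, 1, 2, 5, 4, 7, 6)
  cuts_p <- calibrate_cutpoints(vp, log(1.21), table1_fazekas_pct[perm])
  cum_p <- cumsum(p[perm])[-7]
  each_root <- vapply(cum_p, function(target) uniroot(function(cc)
    integrate(function(v) plogis(cc - log(1.21) * v) *
                dlnorm(v, vp["meanlog"], vp["sdlog"]), 0, Inf,
              rel.tol = 1e-10)$value - target,
    c(-100, 100), tol = 1e-9)$root, numeric(1))
  expect_equal(cuts_p, each_root, tolerance = 1e-5)

  expect_error(calibrate_cutpoints(vp, 0.1, c(0.5, 0, 0.5)),
               "calibration failure")
})

test_that("assign_fazekas follows the latent ordered-logit link", {
  cfg <- default_cfg
  expect_error(assign_fazekas(-1, cfg), "domain error")
  expect_identical(assign_fazekas(numeric(0), cfg), integer(0))

  # far-above-zero cutpoints push volume 0 into category 0
  lo <- cfg; lo$faz_cutpoints <- seq(20, 25)
  expect_identical(assign_fazekas(rep(0, 50), lo, noise_draw = runif(50)),
                   rep(0L, 50))

  # with a shared uniform draw the category is monotone in volume
  u <- 0.37
  cats <- assign_fazekas(seq(0, 120, by = 0.5), cfg, noise_draw = u)
  expect_true(all(diff(cats) >= 0))
  expect_true(all(cats %in% 0:6))
})

test_that("generated cohorts are deterministic, valid, and match the calibration", {
  cfg <- with_n(default_cfg, 30000, seed = 11)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(co1), as.data.frame(co2))

  expect_identical(nrow(generate_cohort(with_n(default_cfg, 0))), 0L)
  expect_false(any(duplicated(co1$patient_id)))
  expect_true(all(co1$wmh_baseline >= 0))
  expect_true(all(co1$fazekas_baseline %in% 0:6))
  expect_true(all(co1$pp > 0 & co1$sbp > co1$dbp))

  pred <- generator_predictions(cfg)
  expect_equal(mean(co1$wmh_baseline), pred$baseline_mean, tolerance = 0.03)
  expect_equal(sd(co1$wmh_baseline), pred$baseline_sd, tolerance = 0.05)
  marg <- tabulate(co1$fazekas_baseline + 1L, 7L) / nrow(co1)
  expect_true(all(abs(marg - pred$fazekas_marginal) < 0.012))
  expect_equal(mean(co1$age), cfg$age_mean, tolerance = 0.01)
  expect_equal(cor(co1$map, co1$pp), cfg$map_pp_corr, tolerance = 0.05)
})

test_that("follow-up simulation obeys the progression model", {
  cfg <- with_n(default_cfg, 500, seed = 5)
  co <- generate_cohort(cfg)

  # near-degenerate model: zero coefficients, intercept 5, vanishing noise
  dg <- cfg
  dg$prog_coefs[] <- 0
  dg$prog_intercept <- 5
  dg$resid_sd <- 1e-9
  fu <- simulate_followup(co, dg)
  expect_equal(fu$wmh_followup, rep(5, nrow(co)), tolerance = 1e-6)

  fu2 <- simulate_followup(co, cfg)
  expect_true(all(fu2$wmh_followup >= 0))
  expect_true(all(fu2$fazekas_followup %in% 0:6))
  # scores may regress, mirroring observed volume decreases
  expect_gt(sum(fu2$fazekas_followup < fu2$fazekas_baseline), 0)

  broken <- co
  broken$wmh_baseline[c(3, 7)] <- NA
  expect_error(simulate_followup(broken, cfg), "data error.*3, 7")
})

test_that("follow-up moments track the quadrature predictions", {
  cfg <- with_n(default_cfg, 30000, seed = 21)
  fu <- simulate_followup(generate_cohort(cfg), cfg)
  pred <- generator_predictions(cfg)
  expect_equal(mean(fu$wmh_followup), pred$followup_mean, tolerance = 0.02)
  expect_equal(sd(fu$wmh_followup), pred$followup_sd, tolerance = 0.03)
  expect_equal(mean(fu$wmh_followup - fu$wmh_baseline),
               pred$mean_progression, tolerance = 0.25)
})

test_that("dropout blanks exactly the follow-up fields, at the calibrated rate", {
  cfg <- with_n(default_cfg, 30000, seed = 31)
  co <- simulate_study(cfg)

  d <- co$dropout == 1L
  expect_true(all(is.na(co$wmh_followup[d])))
  expect_true(all(is.na(co$fazekas_followup[d])))
  expect_true(all(!is.na(co$wmh_followup[!d])))
  expect_identical(co$dropout_reason == "none", !d)
  expect_true(all(!is.na(co$wmh_baseline)))

  pred <- generator_predictions(cfg)
  se <- sqrt(pred$dropout_rate * (1 - pred$dropout_rate) / nrow(co))
  expect_lt(abs(mean(co$dropout) - pred$dropout_rate), 3 * se)

  # flat missingness model at logit(0.28) gives the marginal rate
  flat <- cfg
  flat$dropout_age_coef <- 0; flat$dropout_faz_coef <- 0
  flat$dropout_intercept <- qlogis(0.28)
  co_flat <- apply_dropout(co, flat)
  expect_lt(abs(mean(co_flat$dropout) - 0.28), 3 * sqrt(0.28 * 0.72 / nrow(co)))

  # no one drops out when the intercept is driven to -Inf
  none <- flat; none$dropout_intercept <- -50
  expect_identical(sum(apply_dropout(co, none)$dropout), 0L)
})

test_that("the whole study pipeline is reproducible given the seed", {
  cfg <- with_n(default_cfg, 800, seed = 99)
  expect_identical(as.data.frame(simulate_study(cfg)),
                   as.data.frame(simulate_study(cfg)))
})

test_that("cohort CSV round-trips with empty cells for missing follow-up", {
  cfg <- with_n(default_cfg, 120, seed = 2)
  co <- simulate_study(cfg)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_cohort(co, path)
  raw <- readLines(path)
  expect_match(raw[1], "^\"?patient_id\"?,")
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(co)[, names(back)],
               tolerance = 1e-12, ignore_attr = TRUE)
})
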