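test_that("Whitehead sizes match the independent oracle evaluation", {
  # study Fazekas distribution, OR 1.21 per ml
  expect_identical(
    whitehead_n_per_group(ordinal_design(1.21, fazekas_distribution())),
    as.integer(oracle_whitehead(table1_fazekas_pct, 1.21)))
  expect_identical(
    whitehead_n_per_group(ordinal_design(1.21, fazekas_distribution())), 1384L)

  # two equiprobable categories at OR 2: reduces to the binary two-arm size
  expect_identical(
    whitehead_n_per_group(ordinal_design(2, category_distribution(c(0.5, 0.5)))),
    as.integer(oracle_whitehead(c(0.5, 0.5), 2)))
  expect_identical(
    whitehead_n_per_group(ordinal_design(2, category_distribution(c(0.5, 0.5)))),
    135L)
  # binary cross-check: classical two-proportion normal approximation
  # (control 1/2 vs treatment 1/3 in the upper category) lands nearby
  p1 <- 0.5; p2 <- 1 / 3
  n_2prop <- (qnorm(0.975) + qnorm(0.8))^2 * (p1 * (1 - p1) + p2 * (1 - p2)) /
    (p1 - p2)^2
  expect_lt(abs(135 - n_2prop) / n_2prop, 0.05)
})

test_that("n scales as 1/(log OR)^2 with a fixed denominator and is OR-symmetric", {
  d1 <- ordinal_design(1.2, anchor_n = 1499, anchor_or = 1.2)
  for (or in c(1.1, 1.3, 1.6, 2)) {
    d2 <- d1; d2$odds_ratio <- or
    ratio <- whitehead_n_per_group(d2) / whitehead_n_per_group(d1)
    expect_equal(ratio, (log(1.2) / log(or))^2, tolerance = 6e-3)
  }
  # direction symmetry: exact under a fixed denominator, approximate when
  # the treatment-arm shift re-enters the denominator
  da <- ordinal_design(1.3, anchor_n = 1000, anchor_or = 1.3)
  db <- ordinal_design(1 / 1.3, anchor_n = 1000, anchor_or = 1.3)
  expect_identical(whitehead_n_per_group(da), whitehead_n_per_group(db))
  f <- fazekas_distribution()
  nup <- whitehead_n_per_group(ordinal_design(1.3, f))
  ndown <- whitehead_n_per_group(ordinal_design(1 / 1.3, f))
  expect_lt(abs(nup - ndown) / nup, 0.02)
  # strictly decreasing in |log OR|
  ns <- vapply(c(1.05, 1.1, 1.2, 1.5), function(or)
    whitehead_n_per_group(ordinal_design(or, f)), integer(1))
  expect_true(all(diff(ns) < 0))
})

test_that("the Whitehead denominator respects its bounds", {
  set.seed(40)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    probs <- rgamma(k, 1) + 1e-3
    or <- exp(runif(1, -1, 1))
    if (abs(log(or)) < 0.01) or <- 1.2
    d <- wmhpower:::whitehead_denominator(category_distribution(probs), or)
    expect_gt(d, 0)
    expect_lte(d, 1 - 1 / k^2 + 1e-12)
  }
  # equality at the uniform distribution in the null limit
  du <- wmhpower:::whitehead_denominator(category_distribution(rep(1, 4)),
                                         1 + 1e-9)
  expect_equal(du, 1 - 1 / 16, tolerance = 1e-6)
})

test_that("back-solved denominators invert the formula exactly", {
  d <- backsolve_denominator(1499, 1.2)
  expect_equal(d, 6 * (qnorm(0.975) + qnorm(0.8))^2 / (log(1.2)^2 * 1499),
               tolerance = 1e-12)
  # consistent with the printed Fazekas marginals (~0.94), as it should be
  expect_equal(d, 0.945, tolerance = 1e-3)

  # round trip through the anchored path
  expect_identical(whitehead_n_per_group(
    ordinal_design(1.2, anchor_n = 1499, anchor_or = 1.2)), 1499L)
  d135 <- backsolve_denominator(135, 2)
  expect_identical(whitehead_n_per_group(
    ordinal_design(2, anchor_n = 135, anchor_or = 2)), 135L)
  expect_equal(d135, 1 - sum(((c(0.5, 0.5) + c(2 / 3, 1 / 3)) / 2)^3),
               tolerance = 0.005)

  # random-design round trips stay within rounding slack
  set.seed(41)
  for (i in 1:10) {
    or <- exp(runif(1, 0.05, 0.8))
    n_min <- ceiling(6 * (qnorm(0.975) + qnorm(0.8))^2 / log(or)^2)
    n0 <- n_min + sample(10:5000, 1)
    expect_lte(abs(whitehead_n_per_group(
      ordinal_design(or, anchor_n = n0, anchor_or = or)) - n0), 1L)
  }

  expect_error(backsolve_denominator(2, 3), "outside")
  expect_error(backsolve_denominator(1499, 1), "odds_ratio")
})

test_that("covariate multipliers price stratified adjustment", {
  ov <- fazekas_distribution()
  single <- stratified_distribution(1, list(ov))
  expect_equal(covariate_multiplier(single, ov), 1.0, tolerance = 1e-12)

  st <- stratified_distribution(c(0.5, 0.5), list(
    category_distribution(c(0.8, 0.1, 0.1)),
    category_distribution(c(0.1, 0.1, 0.8))))
  m <- covariate_multiplier(st, category_distribution(c(0.45, 0.1, 0.45)))
  expect_equal(m, (1 - 0.18325) / (1 - 0.514), tolerance = 1e-9)

  # applying the published hypertension multiplier to the base size
  expect_identical(as.integer(ceiling(1499 * 1.00057)), 1500L)

  conc <- structure(list(
    weights = c(0.5, 0.5),
    distributions = list(structure(c(1, 0, 0),
                                   class = "wmh_category_distribution"),
                         category_distribution(c(0.1, 0.1, 0.8)))),
    class = "wmh_stratified_distribution")
  expect_warning(mi <- covariate_multiplier(
    conc, category_distribution(c(0.4, 0.3, 0.3))), "concentrated")
  expect_identical(mi, Inf)
})

test_that("rank-sum sizes come from the enumerated win probability", {
  # enumeration over the four outcome pairs of two 2-category arms
  expect_equal(win_probability(category_distribution(c(0.7, 0.3)),
                               category_distribution(c(0.5, 0.5))),
               0.40, tolerance = 1e-12)
  # a null design has win probability 1/2 and no finite size
  f <- fazekas_distribution()
  expect_equal(win_probability(f, f), 0.5, tolerance = 1e-12)
  expect_error(rank_n_per_group(rank_design(f, f)), "win probability")

  d <- rank_design(category_distribution(c(0.3, 0.7)),
                   category_distribution(c(0.5, 0.5)))
  expect_identical(rank_n_per_group(d),
                   as.integer(oracle_rank_n(c(0.3, 0.7), c(0.5, 0.5))))

  # near-continuous limit: ties vanish and theta ~ 0.6 gives ~131 per group
  k <- 2000
  ctrl <- rep(1 / k, k)
  trt <- c(rep(0, 0.2 * k), rep(1 / k, k - 0.2 * k))  # uniform shift
  dd <- rank_design(category_distribution(trt), category_distribution(ctrl))
  theta <- win_probability(dd$treatment_dist, dd$control_dist)
  expect_equal(theta, 0.6, tolerance = 0.01)
  expect_lt(abs(rank_n_per_group(dd) - 131), 8)
})

test_that("OR sensitivity sweeps anchored at the published base reproduce it", {
  base <- ordinal_design(1.2, anchor_n = 1499, anchor_or = 1.2)
  sweep <- or_sensitivity_sweep(base, c(1.16, 1.2, 1.25))
  expect_identical(sweep$n_per_group, c(2262L, 1499L, 1001L))
  expect_identical(sweep$n_total, 2L * sweep$n_per_group)
  expect_identical(sweep$n_recruit_total, c(5656L, 3748L, 2504L))

  empty <- or_sensitivity_sweep(base, numeric(0))
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty),
                   c("odds_ratio", "n_per_group", "n_total", "n_recruit_total"))
})

test_that("degenerate ordinal designs are rejected", {
  expect_error(ordinal_design(1, fazekas_distribution()), "odds_ratio")
  expect_error(ordinal_design(1.2), "anchor")
  expect_error(category_distribution(c(1, 0, 0)), "degenerate")
})
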