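#' Monte-Carlo trial simulation plan
#'
#' Describes a two-arm trial generator plus the analysis used per replicate.
#' Continuous trials draw normal outcomes with a per-arm mean difference
#' `delta` and SD `sd`, optionally with a baseline covariate explaining
#' `r_squared` of the outcome variance; ordinal trials draw categories from
#' a control distribution and its proportional-odds shift (a single
#' `odds_ratio`) or from heterogeneous per-category cumulative ORs
#' (`category_ors`, length K-1), which deliberately violate proportional
#' odds.
#'
#' @param type `"continuous"` or `"ordinal"`.
#' @param n_per_group Patients per arm.
#' @param method Analysis per replicate: `"z"`, `"t"` or `"ancova"`
#'   (continuous); `"wilcoxon"` or `"po_score"` (ordinal; both are the
#'   tie-corrected rank-sum / proportional-odds score test).
#' @param delta,sd Continuous generator: mean difference and SD.
#' @param r_squared Squared correlation between the baseline covariate and
#'   the outcome (continuous only).
#' @param control_dist Ordinal generator: control-arm
#'   [category_distribution()].
#' @param odds_ratio Common cumulative OR (exact proportional odds).
#' @param category_ors Optional per-category cumulative ORs (length K-1)
#'   replacing `odds_ratio`.
#' @param reps Replicates (default 2000: binomial SE about 0.9 points near
#'   80 percent power).
#' @param alpha Two-sided test level.
#' @param seed Seed for the replicate stream.
#' @return Object of class `wmh_simulation_plan`.
#' @examples
#' plan <- simulation_plan("continuous", n_per_group = 100, delta = 1, sd = 2,
#'                         reps = 500, seed = 7)
#' simulate_power(plan)
#' @export
simulation_plan <- function(type = c("continuous", "ordinal"),
                            n_per_group,
                            method = if (type == "continuous") "z" else "po_score",
                            delta = NULL, sd = NULL, r_squared = 0,
                            control_dist = NULL, odds_ratio = NULL,
                            category_ors = NULL,
                            reps = 2000L, alpha = 0.05, seed = 1L) {
  type <- match.arg(type)
  ok <- list(continuous = c("z", "t", "ancova"),
             ordinal = c("wilcoxon", "po_score"))[[type]]
  if (!is.character(method) || length(method) != 1L || !(method %in% ok))
    stop("configuration error: unknown analysis method `", method,
         "` for ", type, " trials (use ", paste(ok, collapse = ", "), ")",
         call. = FALSE)
  check_number(n_per_group, "n_per_group", lower = 2)
  check_number(reps, "reps", lower = 1)
  check_number(alpha, "alpha", 0, 1, TRUE, TRUE)
  if (type == "continuous") {
    check_number(delta, "delta")
    check_number(sd, "sd", lower = 0, open_lower = TRUE)
    check_number(r_squared, "r_squared", 0, 1, open_upper = TRUE)
  } else {
    control_dist <- as_category_distribution(control_dist)
    if (is.null(category_ors)) {
      check_number(odds_ratio, "odds_ratio", lower = 0, open_lower = TRUE)
      category_ors <- rep(odds_ratio, length(control_dist) - 1L)
    } else if (length(category_ors) != length(control_dist) - 1L) {
      stop("configuration error: `category_ors` must have length K - 1 = ",
           length(control_dist) - 1L, call. = FALSE)
    }
  }
  structure(list(type = type, n_per_group = as.integer(n_per_group),
                 method = method, delta = delta, sd = sd,
                 r_squared = r_squared, control_dist = control_dist,
                 odds_ratio = odds_ratio, category_ors = category_ors,
                 reps = as.integer(reps), alpha = alpha,
                 seed = as.integer(seed)),
            class = "wmh_simulation_plan")
}

# treatment-arm distribution from per-category cumulative ORs; errors if the
# shifted cumulative probabilities are not monotone
shifted_arm_distribution <- function(control_dist, category_ors) {
  gc <- cumsum(unclass(control_dist))
  k <- length(gc)
  gt <- plogis(qlogis(gc[-k]) + log(category_ors))
  if (is.unsorted(gt, strictly = FALSE) || any(gt < 0) || any(gt > 1))
    stop("invalid scenario: per-category ORs give non-monotone cumulative ",
         "probabilities", call. = FALSE)
  category_distribution(diff(c(0, gt, 1)), labels = names(control_dist))
}

# two-sided rank-sum (Mann-Whitney) normal-approximation test with midrank
# tie correction, computed from per-arm category counts; identical to
# wilcox.test(correct = FALSE, exact = FALSE) and to the proportional-odds
# score test for a binary group
rank_sum_p_from_counts <- function(ct, cc) {
  n1 <- sum(ct); n2 <- sum(cc); n <- n1 + n2
  tot <- ct + cc
  cum <- cumsum(tot)
  midrank <- cum - (tot - 1) / 2
  w <- sum(ct * midrank)                      # rank sum of treatment arm
  ew <- n1 * (n + 1) / 2
  tie <- sum(tot^3 - tot) / (n * (n - 1))
  varw <- n1 * n2 / 12 * (n + 1 - tie)
  if (varw <= 0) return(1)
  z <- (w - ew) / sqrt(varw)
  2 * pnorm(-abs(z))
}

#' Estimate power (or type-I error) by Monte-Carlo simulation
#'
#' Runs `reps` independent two-arm trials from the plan's generator,
#' applies the named test at level `alpha`, and reports the rejection
#' fraction with an exact (Clopper-Pearson) 95 percent binomial interval.
#' Seeded and deterministic.
#'
#' @param plan A [simulation_plan()].
#' @return Object of class `wmh_power_estimate`: `power`, `conf_low`,
#'   `conf_high`, `rejections`, `reps`, `seed`, `plan`.
#' @export
simulate_power <- function(plan) {
  stopifnot(inherits(plan, "wmh_simulation_plan"))
  set.seed(plan$seed)
  rej <- if (plan$type == "continuous") {
    simulate_continuous_rejections(plan)$primary
  } else {
    simulate_ordinal_rejections(plan)
  }
  new_power_estimate(sum(rej), plan)
}

new_power_estimate <- function(x, plan) {
  ci <- stats::binom.test(x, plan$reps)$conf.int
  structure(list(power = x / plan$reps, conf_low = ci[1], conf_high = ci[2],
                 rejections = x, reps = plan$reps, seed = plan$seed,
                 plan = plan),
            class = "wmh_power_estimate")
}

#' @export
print.wmh_power_estimate <- function(x, ...) {
  cat(sprintf("Empirical power: %.3f (95%% CI %.3f-%.3f; %d/%d rejections, seed %d)\n",
              x$power, x$conf_low, x$conf_high, x$rejections, x$reps, x$seed))
  invisible(x)
}

# returns list(primary, unadjusted): rejection logicals per replicate.
# `unadjusted` is the plain two-arm test on the same trials, for the
# adjusted-vs-unadjusted comparison.
simulate_continuous_rejections <- function(plan) {
  n <- plan$n_per_group
  crit_z <- qnorm(1 - plan$alpha / 2)
  r2 <- plan$r_squared
  primary <- logical(plan$reps)
  unadj <- logical(plan$reps)
  arm <- rep(c(0, 1), each = n)
  for (i in seq_len(plan$reps)) {
    x <- rnorm(2 * n)                         # baseline covariate (standardised)
    e <- rnorm(2 * n)
    y <- plan$delta * arm + plan$sd * (sqrt(r2) * x + sqrt(1 - r2) * e)
    m1 <- mean(y[arm == 1]); m0 <- mean(y[arm == 0])
    v1 <- stats::var(y[arm == 1]); v0 <- stats::var(y[arm == 0])
    z <- (m1 - m0) / sqrt(v1 / n + v0 / n)
    unadj[i] <- abs(z) > crit_z
    primary[i] <- switch(plan$method,
      z = unadj[i],
      t = stats::t.test(y[arm == 1], y[arm == 0])$p.value < plan$alpha,
      ancova = {
        fit <- stats::lm(y ~ arm + x)
        summary(fit)$coefficients["arm", 4] < plan$alpha
      })
  }
  list(primary = primary, unadjusted = unadj)
}

simulate_ordinal_rejections <- function(plan) {
  pc <- unclass(plan$control_dist)
  pt <- unclass(shifted_arm_distribution(plan$control_dist, plan$category_ors))
  n <- plan$n_per_group
  vapply(seq_len(plan$reps), function(i) {
    ct <- drop(stats::rmultinom(1, n, pt))
    cc <- drop(stats::rmultinom(1, n, pc))
    rank_sum_p_from_counts(ct, cc) < plan$alpha
  }, logical(1))
}

#' Adjusted versus unadjusted analysis of the same simulated trials
#'
#' Simulates continuous trials with a baseline covariate of stated
#' `r_squared` and analyses each replicate both ways: covariate-adjusted
#' linear model and plain two-arm comparison. Quantifies the efficiency gain
#' from baseline adjustment.
#'
#' @param plan A continuous [simulation_plan()] (the `method` field is
#'   ignored; both analyses are run).
#' @return List with elements `adjusted` and `unadjusted`, each a
#'   `wmh_power_estimate`.
#' @export
simulate_covariate_adjustment_gain <- function(plan) {
  stopifnot(inherits(plan, "wmh_simulation_plan"))
  if (plan$type != "continuous")
    stop("configuration error: covariate-adjustment comparison requires a ",
         "continuous plan", call. = FALSE)
  plan$method <- "ancova"
  set.seed(plan$seed)
  rej <- simulate_continuous_rejections(plan)
  list(adjusted = new_power_estimate(sum(rej$primary), plan),
       unadjusted = new_power_estimate(sum(rej$unadjusted), plan))
}

#' Power under proportional-odds violation
#'
#' Builds arm-specific category distributions from heterogeneous
#' per-category cumulative ORs and reports the power of the (misspecified)
#' rank-sum / proportional-odds score analysis. With all ORs equal this
#' reduces exactly to the common-OR path of [simulate_power()].
#'
#' @param control_dist Control-arm [category_distribution()].
#' @param category_ors Cumulative ORs, length K-1.
#' @param n_per_group,reps,alpha,seed As in [simulation_plan()].
#' @param analysis Analysis method (default `"po_score"`).
#' @return A `wmh_power_estimate`.
#' @export
simulate_po_violation <- function(control_dist, category_ors, n_per_group,
                                  analysis = "po_score", reps = 2000L,
                                  alpha = 0.05, seed = 1L) {
  plan <- simulation_plan("ordinal", n_per_group = n_per_group,
                          method = analysis, control_dist = control_dist,
                          category_ors = category_ors, reps = reps,
                          alpha = alpha, seed = seed)
  simulate_power(plan)
}

#' Analytic power of the two-sample z-test
#'
#' `Phi(|delta| / (sd sqrt(2/n)) - z_{1-alpha/2})`, the large-sample power
#' the Monte-Carlo engine is checked against.
#'
#' @param delta Mean difference.
#' @param sd Outcome SD.
#' @param n_per_group Patients per arm.
#' @param alpha Two-sided level.
#' @return Power in `[0, 1]`.
#' @export
analytic_power_z <- function(delta, sd, n_per_group, alpha = 0.05) {
  pnorm(abs(delta) / (sd * sqrt(2 / n_per_group)) - qnorm(1 - alpha / 2))
}
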