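#' Ordinal (Fazekas-score) trial design
#'
#' Parameters of a two-arm trial whose outcome is an ordered categorical
#' scale, powered through Whitehead's proportional-odds sample-size formula.
#' The anticipated treatment effect is a common cumulative odds ratio. The
#' category-distribution term can be supplied explicitly (`control_dist`) or
#' anchored to a known per-group size at a reference OR (`anchor_n`,
#' `anchor_or`) when the underlying distribution is unavailable — the
#' anchor back-solves the formula's denominator exactly.
#'
#' @param odds_ratio Anticipated treatment-vs-control cumulative OR (> 0,
#'   not 1).
#' @param control_dist A [category_distribution()] for the control arm, or
#'   NULL when anchoring.
#' @param alpha Two-sided type-I error.
#' @param power Target power.
#' @param anchor_n,anchor_or Optional anchor: a per-group size known to
#'   correspond to `anchor_or` under the same (unknown) distribution.
#' @param dropout_per_year,years Dropout inflation settings.
#' @return Object of class `wmh_ordinal_design`.
#' @examples
#' # explicit distribution
#' sample_size(ordinal_design(1.21, fazekas_distribution()))
#' # anchored to a known base size
#' sample_size(ordinal_design(1.25, anchor_n = 1499, anchor_or = 1.2))
#' @export
ordinal_design <- function(odds_ratio, control_dist = NULL, alpha = 0.05,
                           power = 0.80, anchor_n = NULL, anchor_or = NULL,
                           dropout_per_year = 0.20, years = 1) {
  check_number(odds_ratio, "odds_ratio", lower = 0, open_lower = TRUE)
  if (odds_ratio == 1)
    stop("configuration error: `odds_ratio` = 1 implies no effect ",
         "(infinite sample size)", call. = FALSE)
  check_number(alpha, "alpha", 0, 1, TRUE, TRUE)
  check_number(power, "power", 0, 1, TRUE, TRUE)
  check_number(dropout_per_year, "dropout_per_year", 0, 1, open_upper = TRUE)
  check_number(years, "years", lower = 1)
  if (is.null(control_dist) && (is.null(anchor_n) || is.null(anchor_or)))
    stop("configuration error: supply `control_dist`, or both `anchor_n` ",
         "and `anchor_or`", call. = FALSE)
  if (!is.null(control_dist)) control_dist <- as_category_distribution(control_dist)
  denominator <- NULL
  if (!is.null(anchor_n)) {
    check_number(anchor_n, "anchor_n", lower = 2)
    check_number(anchor_or, "anchor_or", lower = 0, open_lower = TRUE)
    denominator <- backsolve_denominator(anchor_n, anchor_or, alpha, power)
  }
  structure(list(odds_ratio = odds_ratio, control_dist = control_dist,
                 alpha = alpha, power = power,
                 anchor_n = anchor_n, anchor_or = anchor_or,
                 denominator = denominator,
                 dropout_per_year = dropout_per_year, years = years),
            class = "wmh_ordinal_design")
}

# Whitehead denominator 1 - sum(pbar^3), pbar the mean of the control and
# the OR-shifted treatment category probabilities
whitehead_denominator <- function(control_dist, odds_ratio) {
  pc <- as_category_distribution(control_dist)
  pt <- po_shift(pc, odds_ratio)
  pbar <- (unclass(pc) + unclass(pt)) / 2
  d <- 1 - sum(pbar^3)
  if (d <= 0)
    stop("degenerate distribution: all mass in one category", call. = FALSE)
  d
}

#' Whitehead per-group sample size for an ordinal outcome
#'
#' `n = ceil( 6 (z_{1-alpha/2} + z_{power})^2 /
#' ((log OR)^2 (1 - sum(pbar_k^3))) )` per group (total sample size
#' `12 (z-sum)^2 / (...)`), where `pbar_k` averages the
#' anticipated control and treatment probabilities of category `k`; the
#' treatment distribution is the proportional-odds shift of the control
#' distribution by the design OR. With an anchored design the denominator
#' comes from [backsolve_denominator()] instead, and the result is rounded
#' half-up rather than ceiled, because the anchor size is itself already
#' rounded.
#'
#' @param design An [ordinal_design()].
#' @return Integer patients per group.
#' With two categories this reduces to the standard two-proportion
#' (binary logistic) sample size, and the Monte-Carlo engine confirms the
#' design power at the returned `n` (see [simulate_power()]).
#'
#' @examples
#' whitehead_n_per_group(ordinal_design(1.21, fazekas_distribution()))
#' @export
whitehead_n_per_group <- function(design) {
  stopifnot(inherits(design, "wmh_ordinal_design"))
  num <- 6 * z_sum(design$alpha, design$power)^2
  if (!is.null(design$denominator)) {
    raw <- num / (log(design$odds_ratio)^2 * design$denominator)
    return(as.integer(floor(raw + 0.5)))
  }
  d <- whitehead_denominator(design$control_dist, design$odds_ratio)
  as.integer(ceiling(num / (log(design$odds_ratio)^2 * d)))
}

#' Back-solve the Whitehead denominator from a known sample size
#'
#' Exact pre-rounding inversion of [whitehead_n_per_group()]: recovers the
#' effective `1 - sum(pbar^3)` implied by a printed per-group size at a
#' stated OR, so OR sensitivity sweeps can be run without the (unprinted)
#' category distribution.
#'
#' @param n_per_group Known per-group size (>= 2).
#' @param odds_ratio The OR it was computed for.
#' @param alpha,power Design error rates.
#' @return The effective denominator, in `(0, 1]`.
#' @examples
#' backsolve_denominator(1499, 1.2, 0.05, 0.80)  # ~0.945
#' @export
backsolve_denominator <- function(n_per_group, odds_ratio, alpha = 0.05,
                                  power = 0.80) {
  check_number(n_per_group, "n_per_group", lower = 2)
  check_number(odds_ratio, "odds_ratio", lower = 0, open_lower = TRUE)
  if (odds_ratio == 1)
    stop("configuration error: `odds_ratio` = 1 cannot be inverted",
         call. = FALSE)
  d <- 6 * z_sum(alpha, power)^2 / (log(odds_ratio)^2 * n_per_group)
  if (d <= 0 || d > 1)
    stop("inconsistent inputs: implied denominator ", format(d),
         " outside (0, 1]", call. = FALSE)
  d
}

#' Covariate-adjustment multiplier for ordinal sample sizes
#'
#' The factor by which the base (treatment-only) ordinal sample size must be
#' multiplied to stratify the analysis on a baseline predictor without loss
#' of power: the ratio of the unstratified Whitehead denominator to the
#' prevalence-weighted mean of the within-stratum denominators,
#' `(1 - sum(pbar_overall^3)) / sum_j w_j (1 - sum(pbar_jk^3))`. Applied as
#' `ceil(n_base * multiplier)`. A stratum fully concentrated in one category
#' yields an infinite multiplier (with a warning).
#'
#' @param strata A [stratified_distribution()].
#' @param overall The overall (unstratified) [category_distribution()].
#' @return Multiplier >= 0 (class numeric).
#' @examples
#' ov <- category_distribution(c(0.45, 0.10, 0.45))
#' st <- stratified_distribution(c(0.5, 0.5), list(
#'   category_distribution(c(0.8, 0.1, 0.1)),
#'   category_distribution(c(0.1, 0.1, 0.8))))
#' covariate_multiplier(st, ov)  # 1.68
#' @export
covariate_multiplier <- function(strata, overall) {
  stopifnot(inherits(strata, "wmh_stratified_distribution"))
  overall <- as_category_distribution(overall)
  num <- 1 - sum(unclass(overall)^3)
  dens <- vapply(strata$distributions,
                 function(d) 1 - sum(unclass(d)^3), numeric(1))
  if (any(dens <= 0)) {
    warning("a stratum is fully concentrated in one category: infinite ",
            "multiplier", call. = FALSE)
    return(Inf)
  }
  num / sum(strata$weights * dens)
}

#' Rank-sum (median-comparison) trial design
#'
#' Two-arm design analysed by the Wilcoxon rank-sum test on an ordinal
#' outcome, sized by the tie-corrected Noether approximation.
#'
#' @param treatment_dist,control_dist [category_distribution()]s over the
#'   same categories.
#' @param alpha,power Design error rates.
#' @param dropout_per_year,years Dropout inflation settings.
#' @return Object of class `wmh_rank_design`.
#' @export
rank_design <- function(treatment_dist, control_dist, alpha = 0.05,
                        power = 0.80, dropout_per_year = 0.20, years = 1) {
  treatment_dist <- as_category_distribution(treatment_dist)
  control_dist <- as_category_distribution(control_dist)
  if (length(treatment_dist) != length(control_dist))
    stop("configuration error: arm distributions must share categories",
         call. = FALSE)
  check_number(alpha, "alpha", 0, 1, TRUE, TRUE)
  check_number(power, "power", 0, 1, TRUE, TRUE)
  structure(list(treatment_dist = treatment_dist,
                 control_dist = control_dist, alpha = alpha, power = power,
                 dropout_per_year = dropout_per_year, years = years),
            class = "wmh_rank_design")
}

#' Win probability P(T > C) + 0.5 P(T = C)
#'
#' Computed exactly by enumeration over category pairs; the Mann-Whitney
#' effect measure driving the rank-sum sample size.
#'
#' @param treatment_dist,control_dist [category_distribution()]s.
#' @return Theta in `[0, 1]`.
#' @export
win_probability <- function(treatment_dist, control_dist) {
  t <- unclass(as_category_distribution(treatment_dist))
  c_ <- unclass(as_category_distribution(control_dist))
  ccum <- cumsum(c_)
  sum(t * (c(0, ccum[-length(c_)]) + 0.5 * c_))
}

#' Rank-sum per-group sample size (tie-corrected Noether approximation)
#'
#' `n = ceil( (z_{1-alpha/2} + z_{power})^2 (1 - sum(tbar_k^3)) /
#' (6 (theta - 1/2)^2) )`, with `theta` the win probability
#' [win_probability()] and `tbar_k` the combined-sample (equal-allocation
#' average) category probabilities; the tie term `1 - sum(tbar^3)` tends to
#' 1 in the no-tie continuous limit.
#'
#' @param design A [rank_design()].
#' @return Integer patients per group.
#' @export
rank_n_per_group <- function(design) {
  stopifnot(inherits(design, "wmh_rank_design"))
  theta <- win_probability(design$treatment_dist, design$control_dist)
  if (abs(theta - 0.5) < 1e-12)
    stop("configuration error: win probability 1/2 (no effect); ",
         "sample size is unbounded", call. = FALSE)
  tbar <- (unclass(design$treatment_dist) + unclass(design$control_dist)) / 2
  tie_term <- 1 - sum(tbar^3)
  as.integer(ceiling(z_sum(design$alpha, design$power)^2 * tie_term /
                       (6 * (theta - 0.5)^2)))
}

#' @rdname sample_size
#' @export
sample_size.wmh_ordinal_design <- function(design, ...) {
  new_sample_size(whitehead_n_per_group(design), design,
                  design$years, design$dropout_per_year)
}

#' @rdname sample_size
#' @export
sample_size.wmh_rank_design <- function(design, ...) {
  new_sample_size(rank_n_per_group(design), design,
                  design$years, design$dropout_per_year)
}

#' Odds-ratio sensitivity sweep
#'
#' Recomputes the ordinal sample size over a list of ORs with the
#' category-distribution term held fixed (explicit distribution, or the
#' anchored denominator), exposing how sharply the required size reacts to
#' the assumed OR.
#'
#' @param base An [ordinal_design()] supplying the fixed denominator and
#'   error rates.
#' @param or_values Numeric vector of ORs to evaluate.
#' @return Data frame: `odds_ratio`, `n_per_group`, `n_total`,
#'   `n_recruit_total`.
#' @examples
#' base <- ordinal_design(1.2, anchor_n = 1499, anchor_or = 1.2)
#' or_sensitivity_sweep(base, c(1.16, 1.2, 1.25))
#' @export
or_sensitivity_sweep <- function(base, or_values) {
  stopifnot(inherits(base, "wmh_ordinal_design"))
  out <- lapply(or_values, function(or) {
    d <- base
    d$odds_ratio <- or
    if (or == 1) stop("configuration error: OR 1 in sweep", call. = FALSE)
    res <- sample_size(d)
    data.frame(odds_ratio = or, n_per_group = res$n_per_group,
               n_total = res$n_total, n_recruit_total = res$n_recruit_total)
  })
  if (!length(out))
    return(data.frame(odds_ratio = numeric(0), n_per_group = integer(0),
                      n_total = integer(0), n_recruit_total = integer(0)))
  do.call(rbind, out)
}
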