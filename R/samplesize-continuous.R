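#' Continuous (WMH-volume) trial design
#'
#' Parameters of a two-arm trial whose outcome is follow-up WMH volume: the
#' treatment is assumed to stabilise volumes while the control arm
#' progresses by `delta_per_year` ml per year.
#'
#' @param delta_per_year Assumed between-group difference accruing per year
#'   of follow-up (ml; the base design uses 1).
#' @param sd Outcome SD (ml; the cohort's follow-up SD is 23.3).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power (default 0.80).
#' @param r_squared Fraction of outcome variance explained by the adjustment
#'   covariates, in `[0, 1)`; 0 means an unadjusted comparison.
#' @param years Follow-up duration in years (>= 1).
#' @param dropout_per_year Expected dropout fraction per year, in `[0, 1)`.
#' @return Object of class `wmh_continuous_design`.
#' @examples
#' sample_size(continuous_design(r_squared = 0.90))
#' @export
continuous_design <- function(delta_per_year = 1, sd = 23.3, alpha = 0.05,
                              power = 0.80, r_squared = 0, years = 1,
                              dropout_per_year = 0.20) {
  if (!is.numeric(delta_per_year) || length(delta_per_year) != 1L ||
      !is.finite(delta_per_year) || delta_per_year == 0)
    stop("configuration error: `delta_per_year` must be a nonzero number ",
         "(a zero difference needs an infinite sample)", call. = FALSE)
  check_number(sd, "sd", lower = 0, open_lower = TRUE)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(power, "power", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(r_squared, "r_squared", lower = 0, upper = 1,
               open_upper = TRUE)
  check_number(years, "years", lower = 1)
  check_number(dropout_per_year, "dropout_per_year", lower = 0, upper = 1,
               open_upper = TRUE)
  structure(list(delta_per_year = delta_per_year, sd = sd, alpha = alpha,
                 power = power, r_squared = r_squared, years = years,
                 dropout_per_year = dropout_per_year),
            class = "wmh_continuous_design")
}

#' Per-group sample size for a continuous-outcome trial
#'
#' Two-group normal-approximation formula with covariate deflation:
#' `n = ceil( 2 (z_{1-alpha/2} + z_{power})^2 sd^2 (1 - R^2) /
#' (delta_per_year * years)^2 )`. The outcome SD is held constant across
#' follow-up durations; only the accrued difference scales with `years`.
#'
#' @param design A [continuous_design()].
#' @param t_correction Use the iterated t-quantile correction instead of
#'   normal quantiles (default FALSE; the normal formula is the
#'   conventional one).
#' @return Integer patients per group.
#' @examples
#' n_per_group_continuous(continuous_design())          # unadjusted
#' n_per_group_continuous(continuous_design(r_squared = 0.90))
#' @export
n_per_group_continuous <- function(design, t_correction = FALSE) {
  stopifnot(inherits(design, "wmh_continuous_design"))
  check_flag(t_correction, "t_correction")
  delta <- design$delta_per_year * design$years
  raw <- 2 * z_sum(design$alpha, design$power)^2 * design$sd^2 *
    (1 - design$r_squared) / delta^2
  if (!t_correction) return(as.integer(ceiling(raw)))
  # iterate the t-based formula to a fixed point
  n <- max(ceiling(raw), 2)
  for (i in 1:50) {
    df <- 2 * n - 2
    zt <- qt(1 - design$alpha / 2, df) + qt(design$power, df)
    n_new <- ceiling(2 * zt^2 * design$sd^2 * (1 - design$r_squared) / delta^2)
    if (n_new == n) break
    n <- n_new
  }
  as.integer(n)
}

#' Deflate an unadjusted sample size by covariate R-squared
#'
#' `ceil(n_unadjusted * (1 - r_squared))`: the reduction obtained by
#' including covariates that explain `r_squared` of the outcome variance in
#' the analysis. Equivalent (to within rounding of the pre-rounded input) to
#' setting `r_squared` inside [n_per_group_continuous()].
#'
#' @param n_unadjusted Unadjusted sample size (per group or total).
#' @param r_squared In `[0, 1)`.
#' @return Integer adjusted sample size.
#' @examples
#' apply_r2_adjustment(8508, 0.88)
#' @export
apply_r2_adjustment <- function(n_unadjusted, r_squared) {
  check_number(n_unadjusted, "n_unadjusted", lower = 1)
  check_number(r_squared, "r_squared", lower = 0, upper = 1, open_upper = TRUE)
  as.integer(ceiling(n_unadjusted * (1 - r_squared)))
}

#' Inflate a sample size for expected dropout
#'
#' Retention after `years` of follow-up at a per-year dropout rate is
#' `(1 - rate)^years`; recruitment per group is
#' `ceil(n_per_group / retention)` and the total is twice that
#' (ceil-then-double).
#'
#' @param n_per_group Required completers per group.
#' @param rate_per_year Dropout fraction per year, in `[0, 1)`.
#' @param years Follow-up duration (default 1).
#' @return List with `n_recruit_per_group` and `n_recruit_total`.
#' @examples
#' inflate_dropout(821, 0.20, years = 1)   # 1027 per group, 2054 total
#' inflate_dropout(205, 0.20, years = 2)   # retention 0.64: 321 / 642
#' @export
inflate_dropout <- function(n_per_group, rate_per_year, years = 1) {
  check_number(n_per_group, "n_per_group", lower = 1)
  check_number(rate_per_year, "rate_per_year", lower = 0, upper = 1,
               open_upper = TRUE)
  check_number(years, "years", lower = 1)
  retention <- (1 - rate_per_year)^years
  per_group <- as.integer(ceiling(n_per_group / retention))
  list(n_recruit_per_group = per_group,
       n_recruit_total = 2L * per_group)
}

#' Full sample-size result for a trial design
#'
#' Dispatches to the engine matching the design class
#' ([n_per_group_continuous()], [whitehead_n_per_group()] or
#' [rank_n_per_group()]), then applies dropout inflation; the result echoes
#' its inputs.
#'
#' @param design A `wmh_continuous_design`, `wmh_ordinal_design` or
#'   `wmh_rank_design`.
#' @param ... Passed to the engine.
#' @return Object of class `wmh_sample_size`: `n_per_group`, `n_total`,
#'   `n_recruit_per_group`, `n_recruit_total`, `design`.
#' @export
sample_size <- function(design, ...) UseMethod("sample_size")

new_sample_size <- function(n_per_group, design, years, dropout) {
  infl <- inflate_dropout(n_per_group, dropout, years)
  structure(list(n_per_group = as.integer(n_per_group),
                 n_total = 2L * as.integer(n_per_group),
                 n_recruit_per_group = infl$n_recruit_per_group,
                 n_recruit_total = infl$n_recruit_total,
                 design = design),
            class = "wmh_sample_size")
}

#' @rdname sample_size
#' @export
sample_size.wmh_continuous_design <- function(design, ...) {
  new_sample_size(n_per_group_continuous(design, ...), design,
                  design$years, design$dropout_per_year)
}

#' @export
print.wmh_sample_size <- function(x, ...) {
  cat("Sample size:", fmt_int(x$n_per_group), "per group,",
      fmt_int(x$n_total), "total,",
      fmt_int(x$n_recruit_total), "after dropout allowance\n")
  invisible(x)
}
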