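# shared fixtures, built in code once per test run

# calibrated defaults (deterministic); cohort size overridden per test
default_cfg <- default_generator_config(n_patients = 264L, seed = 1L)

with_n <- function(cfg, n, seed = cfg$seed) {
  cfg$n_patients <- as.integer(n)
  cfg$seed <- as.integer(seed)
  cfg
}

# independent oracle: Whitehead per-group size evaluated directly from its
# definition (cumulative-logit shift, two-arm average, closed form)
oracle_whitehead <- function(control_probs, or, alpha = 0.05, power = 0.8) {
  pc <- control_probs / sum(control_probs)
  gc <- cumsum(pc)[-length(pc)]
  gt <- 1 / (1 + exp(-(log(gc / (1 - gc)) + log(or))))
  pt <- diff(c(0, gt, 1))
  pbar <- (pc + pt) / 2
  zs <- qnorm(0.975) + qnorm(power)
  ceiling(6 * zs^2 / (log(or)^2 * (1 - sum(pbar^3))))
}

# independent oracle: tie-corrected Noether rank-sum size from first
# principles (enumerated win probability)
oracle_rank_n <- function(t_probs, c_probs, alpha = 0.05, power = 0.8) {
  t_probs <- t_probs / sum(t_probs); c_probs <- c_probs / sum(c_probs)
  theta <- 0
  for (i in seq_along(t_probs)) for (j in seq_along(c_probs)) {
    if (i > j) theta <- theta + t_probs[i] * c_probs[j]
    if (i == j) theta <- theta + 0.5 * t_probs[i] * c_probs[j]
  }
  tbar <- (t_probs + c_probs) / 2
  zs <- qnorm(1 - alpha / 2) + qnorm(power)
  ceiling(zs^2 * (1 - sum(tbar^3)) / (6 * (theta - 0.5)^2))
}

table1_fazekas_pct <- c(4.2, 9.0, 36.8, 12.6, 15.3, 9.0, 13.2)
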