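# internal helpers shared across modules

z_sum <- function(alpha, power) qnorm(1 - alpha / 2) + qnorm(power)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("configuration error: `", name, "` must be a single finite number",
         call. = FALSE)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop("configuration error: `", name, "` = ", format(x),
         " is outside the allowed range ",
         if (open_lower) "(" else "[", lower, ", ", upper,
         if (open_upper) ")" else "]", call. = FALSE)
  x
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop("configuration error: `", name, "` must be TRUE or FALSE", call. = FALSE)
  x
}

# mean of N(mu, sd) left-truncated at zero
truncnorm_mean <- function(mu, sd) {
  z <- mu / sd
  mu + sd * exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
}

# draw from N(mu, sd) conditioned on being >= 0, by inverse CDF
# (distributionally identical to resampling the noise until nonnegative)
rtruncnorm0 <- function(n, mu, sd, u = runif(n)) {
  p_lo <- pnorm(0, mean = mu, sd = sd)
  q <- pmin(p_lo + u * (1 - p_lo), 1 - 1e-16)
  out <- qnorm(q, mean = mu, sd = sd)
  pmax(out, 0)
}

# expectation of g(V) under the lognormal baseline-volume law; g vectorised
lnorm_expect <- function(g, meanlog, sdlog) {
  integrate(function(v) g(v) * dlnorm(v, meanlog, sdlog),
            lower = 0, upper = Inf,
            rel.tol = 1e-10, abs.tol = 1e-12)$value
}

fmt_int <- function(x) formatC(x, format = "d", big.mark = ",")
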