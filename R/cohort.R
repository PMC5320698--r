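cohort_columns <- function() {
  c("patient_id", "age", "map", "pp", "sbp", "dbp", "hypertension",
    "diabetes", "smoker", "hyperlipidaemia", "subtype", "wmh_baseline",
    "fazekas_baseline", "wmh_followup", "fazekas_followup", "dropout",
    "dropout_reason")
}

dropout_reasons <- function() {
  c("declined", "unwell", "died", "other", "incomplete_scan")
}

# observed non-completer reason frequencies: 33 declined, 24 unwell, 5 died,
# 6 other, 6 incomplete scans (of 74)
dropout_reason_probs <- function() {
  c(declined = 33, unwell = 24, died = 5, other = 6, incomplete_scan = 6) / 74
}

new_cohort <- function(df, config, stage) {
  structure(df, class = c("wmh_cohort", "data.frame"),
            config = config, stage = stage)
}

#' Generate a synthetic mild-stroke cohort (baseline stage)
#'
#' Draws one patient per row: age, blood-pressure summaries (MAP and PP
#' bivariate normal, PP kept positive; systolic/diastolic derived as
#' `sbp = map + 2 pp / 3`, `dbp = map - pp / 3`), binary risk factors,
#' stroke subtype, lognormal baseline WMH volume and the baseline Fazekas
#' score from the latent ordered-logit link. Follow-up fields are left
#' missing; see [simulate_followup()] and [apply_dropout()], or
#' [simulate_study()] for the full pipeline. Deterministic given
#' `config$seed`.
#'
#' @param config A [generator_config()] (usually
#'   [default_generator_config()]).
#' @return A `wmh_cohort` data frame with `config$n_patients` rows.
#' @examples
#' head(generate_cohort(default_generator_config(n_patients = 20)))
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  n <- as.integer(config$n_patients)
  set.seed(config$seed)
  if (n == 0L) {
    df <- as.data.frame(lapply(cohort_columns(), function(x) logical(0)))
    names(df) <- cohort_columns()
    return(new_cohort(df, config, "baseline"))
  }
  age <- rnorm(n, config$age_mean, config$age_sd)
  # (MAP, PP) bivariate normal; redraw pairs until PP > 0 so sbp > dbp
  draw_bp <- function(m) {
    z1 <- rnorm(m); z2 <- rnorm(m)
    rho <- config$map_pp_corr
    cbind(map = config$map_mean + config$map_sd * z1,
          pp = config$pp_mean +
            config$pp_sd * (rho * z1 + sqrt(1 - rho^2) * z2))
  }
  bp <- draw_bp(n)
  bad <- which(bp[, "pp"] <= 0)
  while (length(bad)) {
    bp[bad, ] <- draw_bp(length(bad))
    bad <- bad[bp[bad, "pp"] <= 0]
  }
  vol <- rlnorm(n, config$vol_log_mean, config$vol_log_sd)
  faz <- assign_fazekas(vol, config, noise_draw = runif(n))
  df <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = age,
    map = bp[, "map"], pp = bp[, "pp"],
    sbp = bp[, "map"] + 2 * bp[, "pp"] / 3,
    dbp = bp[, "map"] - bp[, "pp"] / 3,
    hypertension = rbinom(n, 1, config$prev_hypertension),
    diabetes = rbinom(n, 1, config$prev_diabetes),
    smoker = rbinom(n, 1, config$prev_smoker),
    hyperlipidaemia = rbinom(n, 1, config$prev_hyperlipidaemia),
    subtype = rbinom(n, 1, config$prev_lacunar),
    wmh_baseline = vol,
    fazekas_baseline = faz,
    wmh_followup = NA_real_,
    fazekas_followup = NA_integer_,
    dropout = 0L,
    dropout_reason = "none",
    stringsAsFactors = FALSE)
  new_cohort(df, config, "baseline")
}

#' Draw a Fazekas score from the latent ordered-logit link
#'
#' Maps a WMH volume to a Fazekas category 0--6 by inverting the cumulative
#' ordered-logit distribution with linear predictor
#' `faz_slope * volume` and the configured cutpoints, using a supplied
#' uniform draw. Stochastically increasing in volume.
#'
#' @param volume Nonnegative WMH volume(s), ml.
#' @param config A [generator_config()].
#' @param noise_draw Uniform(0,1) draw(s), recycled to `length(volume)`.
#' @return Integer vector of Fazekas scores in `0:6`.
#' @export
assign_fazekas <- function(volume, config, noise_draw = runif(length(volume))) {
  if (any(volume < 0, na.rm = TRUE))
    stop("domain error: `volume` must be nonnegative", call. = FALSE)
  if (length(volume) == 0L) return(integer(0))
  u <- rep_len(noise_draw, length(volume))
  cum <- vapply(config$faz_cutpoints,
                function(cc) plogis(cc - config$faz_slope * volume),
                numeric(length(volume)))
  cum <- matrix(cum, nrow = length(volume))
  as.integer(rowSums(u > cum))
}

#' Simulate 1-year follow-up WMH measures
#'
#' Adds follow-up WMH volume and Fazekas score to a baseline cohort. The
#' follow-up volume is the linear progression model
#' `prog_intercept + prog_coefs . x` plus Normal(0, `resid_sd`) noise
#' constrained to a nonnegative total (truncated-normal noise, equivalent to
#' redrawing the noise until the volume is nonnegative). The follow-up
#' Fazekas score is re-read from the follow-up volume through the same
#' latent link, so scores can regress, mirroring observed volume decreases.
#'
#' @param cohort A `wmh_cohort` with complete baseline fields.
#' @param config A [generator_config()].
#' @param seed Seed for this stage; defaults to `config$seed + 1`.
#' @return The cohort with `wmh_followup` and `fazekas_followup` filled in.
#' @export
simulate_followup <- function(cohort, config, seed = config$seed + 1L) {
  validate_generator_config(config)
  need <- c("wmh_baseline", "fazekas_baseline", predictor_columns())
  miss <- which(!stats::complete.cases(cohort[, unique(need)]))
  if (length(miss))
    stop("data error: missing baseline fields in rows ",
         paste(utils::head(miss, 10L), collapse = ", "),
         if (length(miss) > 10L) " ..." else "", call. = FALSE)
  n <- nrow(cohort)
  if (n == 0L) return(cohort)
  set.seed(seed)
  cols <- predictor_columns()
  x <- as.matrix(as.data.frame(cohort)[, cols])
  colnames(x) <- names(cols)
  lp <- config$prog_intercept +
    drop(x %*% config$prog_coefs[names(cols)])
  cohort$wmh_followup <- rtruncnorm0(n, lp, config$resid_sd)
  cohort$fazekas_followup <- assign_fazekas(cohort$wmh_followup, config,
                                            noise_draw = runif(n))
  attr(cohort, "stage") <- "followup"
  cohort
}

#' Apply informative dropout to a simulated cohort
#'
#' Draws a dropout indicator from the logistic missingness model in age and
#' baseline Fazekas score (older, higher-Fazekas patients drop out more),
#' assigns a reason with the observed non-completer frequencies, and blanks
#' the follow-up fields of dropouts (including incomplete scans, which count
#' as dropouts for volume analyses).
#'
#' @param cohort A `wmh_cohort` (typically after [simulate_followup()]).
#' @param config A [generator_config()].
#' @param seed Seed for this stage; defaults to `config$seed + 2`.
#' @return The cohort with `dropout`, `dropout_reason` set and follow-up
#'   fields blanked for dropouts.
#' @export
apply_dropout <- function(cohort, config, seed = config$seed + 2L) {
  validate_generator_config(config)
  n <- nrow(cohort)
  if (n == 0L) return(cohort)
  set.seed(seed)
  p <- plogis(config$dropout_intercept +
                config$dropout_age_coef * cohort$age +
                config$dropout_faz_coef * cohort$fazekas_baseline)
  drop <- as.integer(runif(n) < p)
  reason <- rep("none", n)
  nd <- sum(drop)
  if (nd > 0)
    reason[drop == 1L] <- sample(dropout_reasons(), nd, replace = TRUE,
                                 prob = dropout_reason_probs())
  cohort$dropout <- drop
  cohort$dropout_reason <- reason
  cohort$wmh_followup[drop == 1L] <- NA_real_
  cohort$fazekas_followup[drop == 1L] <- NA_integer_
  attr(cohort, "stage") <- "complete"
  cohort
}

#' Run the full synthetic-cohort pipeline
#'
#' [generate_cohort()], then [simulate_followup()], then [apply_dropout()],
#' each stage seeded deterministically from `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A complete `wmh_cohort`.
#' @examples
#' cohort <- simulate_study(default_generator_config(n_patients = 100))
#' table(cohort$dropout)
#' @export
simulate_study <- function(config) {
  apply_dropout(simulate_followup(generate_cohort(config), config), config)
}

#' @export
print.wmh_cohort <- function(x, ...) {
  cat(sprintf("Synthetic mild-stroke cohort: %d patients (stage: %s)\n",
              nrow(x), attr(x, "stage") %||% "unknown"))
  if (nrow(x) > 0) {
    cat(sprintf("  baseline WMH volume: mean %.1f ml, SD %.1f ml\n",
                mean(x$wmh_baseline), sd(x$wmh_baseline)))
    if (any(!is.na(x$wmh_followup)))
      cat(sprintf("  completers: %d (%.0f%%)\n", sum(!is.na(x$wmh_followup)),
                  100 * mean(!is.na(x$wmh_followup))))
  }
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a cohort as CSV
#'
#' Fixed-header CSV with one column per patient field; missing follow-up is
#' encoded as an empty cell.
#'
#' @param cohort A `wmh_cohort`.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `wmh_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, cohort_columns()], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols))
    stop("data error: cohort file lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$dropout_reason[is.na(df$dropout_reason)] <- "none"
  new_cohort(df[, cohort_columns()], NULL,
             if (any(df$dropout == 1L)) "complete" else "followup")
}
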