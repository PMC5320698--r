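#' Reference designs for hypothetical WMH-progression trials
#'
#' The thirteen worked-example analysis plans used throughout the package
#' documentation: six WMH-volume designs (unadjusted; adjusted for baseline
#' volume, age, baseline Fazekas, or all ten predictors; all-predictor with
#' 2-year follow-up) and seven Fazekas-score designs (ORs 1.2 / 1.25 / 1.16;
#' covariate multipliers for baseline Fazekas, hypertension and age; and the
#' median-comparison rank-sum design). `n_per_group` holds the published
#' per-group completer requirement of each plan; rows whose inputs are fully
#' specified can also be recomputed from the engines (see the vignette).
#'
#' @return Data frame: `label`, `outcome`, `n_per_group`, `years`.
#' @export
hypothetical_trial_designs <- function() {
  data.frame(
    label = c(
      "Treatment group only (assumed difference 1 ml)",
      "Treatment group + baseline WMH volume (R2 = 0.88)",
      "Treatment group + age (R2 = 0.19)",
      "Treatment group + baseline Fazekas score (R2 = 0.69)",
      "Treatment group + all predictors (R2 = 0.90)",
      "Treatment group + all predictors (R2 = 0.90), 2-year follow-up",
      "Treatment group only (assumed OR 1.2)",
      "Treatment group only (assumed OR 1.25, upper 95% CI)",
      "Treatment group only (assumed OR 1.16, lower 95% CI)",
      "Treatment group + baseline Fazekas (multiplier 5.04)",
      "Treatment group + baseline hypertension (multiplier 1.00057)",
      "Treatment group + baseline age (multiplier 1.012)",
      "Treatment group only (median increase 0.5)"),
    outcome = c(rep("WMH volume", 6), rep("Fazekas score", 7)),
    n_per_group = c(8508L, 987L, 6872L, 2628L, 821L, 205L,
                    1499L, 1001L, 2262L, 7554L, 1500L, 1515L, 87216L),
    years = c(1, 1, 1, 1, 1, 2, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
}

#' Build a trial design table
#'
#' Assembles the per-group / total / dropout-inflated sample sizes for a
#' list of designs into one table. Each entry is either a design object
#' (dispatched to its engine via [sample_size()]) or a list with a fixed
#' `n_per_group` (plus optional `years`), for plans whose per-group size is
#' known but whose inputs are not. Dropout inflation is applied uniformly
#' via [inflate_dropout()]. Engine errors flag the row but leave the table
#' intact.
#'
#' @param designs Named list (names become labels) of design objects or
#'   `list(n_per_group = , years = , outcome = )` entries.
#' @param dropout_per_year Dropout rate used for rows that do not carry
#'   their own (default 0.20).
#' @return Data frame of class `wmh_design_table`: `label`, `outcome`,
#'   `n_per_group`, `n_total`, `n_recruit_total`, `years`, `note`.
#' @examples
#' build_design_table(list(
#'   unadjusted = continuous_design(),
#'   adjusted = continuous_design(r_squared = 0.90)))
#' @export
build_design_table <- function(designs, dropout_per_year = 0.20) {
  if (!length(designs))
    return(structure(data.frame(label = character(0), outcome = character(0),
                                n_per_group = integer(0), n_total = integer(0),
                                n_recruit_total = integer(0),
                                years = numeric(0), note = character(0)),
                     class = c("wmh_design_table", "data.frame")))
  labels <- names(designs)
  if (is.null(labels)) labels <- paste("design", seq_along(designs))
  rows <- Map(function(d, lab) {
    row <- data.frame(label = lab, outcome = NA_character_,
                      n_per_group = NA_integer_, n_total = NA_integer_,
                      n_recruit_total = NA_integer_, years = NA_real_,
                      note = "", stringsAsFactors = FALSE)
    tryCatch({
      if (inherits(d, c("wmh_continuous_design", "wmh_ordinal_design",
                        "wmh_rank_design"))) {
        res <- sample_size(d)
        row$outcome <- if (inherits(d, "wmh_continuous_design"))
          "WMH volume" else "Fazekas score"
        row$n_per_group <- res$n_per_group
        row$n_total <- res$n_total
        row$n_recruit_total <- res$n_recruit_total
        row$years <- d$years
      } else {
        years <- d$years %||% 1
        infl <- inflate_dropout(d$n_per_group,
                                d$dropout_per_year %||% dropout_per_year,
                                years)
        row$outcome <- d$outcome %||% NA_character_
        row$n_per_group <- as.integer(d$n_per_group)
        row$n_total <- 2L * as.integer(d$n_per_group)
        row$n_recruit_total <- infl$n_recruit_total
        row$years <- years
      }
      row
    }, error = function(e) {
      row$note <- conditionMessage(e)
      row
    })
  }, designs, labels)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("wmh_design_table", "data.frame")
  out
}

#' @export
print.wmh_design_table <- function(x, ...) {
  cat("Sample sizes for hypothetical randomised controlled trials\n")
  if (!nrow(x)) {
    cat("  (no designs)\n")
    return(invisible(x))
  }
  disp <- as.data.frame(x)
  for (col in c("n_per_group", "n_total", "n_recruit_total"))
    disp[[col]] <- ifelse(is.na(disp[[col]]), "-", fmt_int(disp[[col]]))
  disp$years <- NULL
  names(disp) <- c("Analysis plan", "Outcome", "n per group", "Total",
                   "Dropout allowance", "Note")
  if (all(disp$Note == "")) disp$Note <- NULL
  print(disp, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Write a design table as CSV (plain numbers, no separators)
#'
#' @param x A `wmh_design_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' End-to-end pipeline: generate, analyse, size, verify
#'
#' Runs the whole workflow on one configuration: simulate a cohort, fit the
#' analysis stage (progression regressions, VIFs, ordinal OR, dropout
#' comparison), calibrate trial designs from the fitted quantities
#' (follow-up SD, multivariable R-squared, OR per ml), compute sample sizes
#' with dropout inflation, and optionally verify the continuous design by
#' Monte-Carlo simulation. All artefacts (cohort CSV, tidy results, design
#' table CSV and text, JSON-like summary log with seeds) are written to
#' `output_dir` when given.
#'
#' @param config A [generator_config()]; default
#'   [default_generator_config()].
#' @param output_dir Directory for artefacts, or NULL to skip writing.
#' @param verify_power Run the Monte-Carlo check of the adjusted continuous
#'   design (default FALSE; adds ~seconds).
#' @param reps Replicates for the verification.
#' @return List of class `wmh_report`: `cohort`, `fits`, `vif`,
#'   `ordinal_fit`, `comparison`, `design_table`, `power_check`, `seed`.
#' @examples
#' rep <- run_pipeline(default_generator_config(n_patients = 300, seed = 9))
#' rep$design_table
#' @export
run_pipeline <- function(config = default_generator_config(),
                         output_dir = NULL, verify_power = FALSE,
                         reps = 1000L) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", what, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("generate", simulate_study(config))
  fits <- stage("analyse", fit_progression_models(cohort))
  vif <- stage("analyse", compute_vif(cohort))
  ord <- stage("analyse", fit_volume_to_fazekas(cohort))
  cmp <- stage("analyse", compare_dropout_groups(cohort))
  followup_sd <- sd(cohort$wmh_followup, na.rm = TRUE)
  designs <- list(
    "Treatment group only" =
      continuous_design(sd = followup_sd),
    "Treatment group + all predictors (fitted R2)" =
      continuous_design(sd = followup_sd,
                        r_squared = min(fits$r_squared, 1 - 1e-6)),
    "Fazekas outcome, fitted OR per ml" =
      ordinal_design(ord$odds_ratio,
                     category_distribution(
                       tabulate(cohort$fazekas_baseline + 1L, 7L) +
                         0.5)))  # light smoothing: small cohorts can miss a category
  table <- stage("samplesize", build_design_table(designs))
  power_check <- NULL
  if (verify_power) {
    d <- designs[[2]]
    n <- n_per_group_continuous(d)
    power_check <- stage("power", simulate_power(simulation_plan(
      "continuous", n_per_group = n, method = "ancova", delta = 1,
      sd = followup_sd, r_squared = d$r_squared, reps = reps,
      seed = config$seed + 10L)))
  }
  report <- structure(list(cohort = cohort, fits = fits, vif = vif,
                           ordinal_fit = ord, comparison = cmp,
                           design_table = table, power_check = power_check,
                           seed = config$seed,
                           version = as.character(utils::packageVersion("wmhpower"))),
                      class = "wmh_report")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(output_dir, "cohort.csv"))
    write_analysis_csv(fits, file.path(output_dir, "progression_models.csv"))
    write_analysis_csv(cmp, file.path(output_dir, "dropout_comparison.csv"))
    write_design_table(table, file.path(output_dir, "design_table.csv"))
    txt <- file.path(output_dir, "design_table.txt")
    sink(txt); print(table); sink()
    log <- file.path(output_dir, "run_log.txt")
    writeLines(c(
      paste("wmhpower version:", report$version),
      paste("seed:", config$seed),
      paste("n_patients:", config$n_patients),
      paste("fitted follow-up SD (ml):", format(followup_sd)),
      paste("fitted multivariable R-squared:", format(fits$r_squared)),
      paste("fitted OR per ml:", format(ord$odds_ratio))), log)
  }
  report
}

#' @export
print.wmh_report <- function(x, ...) {
  cat("WMH trial-design report (seed ", x$seed, ", wmhpower ",
      x$version, ")\n\n", sep = "")
  cat(sprintf("Cohort: %d patients, %d completers\n", nrow(x$cohort),
              sum(!is.na(x$cohort$wmh_followup))))
  cat(sprintf("Fitted: follow-up SD %.1f ml, R-squared %.3f, OR/ml %.3f\n\n",
              sd(x$cohort$wmh_followup, na.rm = TRUE), x$fits$r_squared,
              x$ordinal_fit$odds_ratio))
  print(x$design_table)
  if (!is.null(x$power_check)) {
    cat("\nMonte-Carlo verification of the adjusted continuous design:\n  ")
    print(x$power_check)
  }
  invisible(x)
}
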