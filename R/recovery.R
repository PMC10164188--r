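# Parameter-recovery study: compare per-subject estimates against the
# known generating values of a simulated cohort.

#' Compare fitted parameters with simulation truth
#'
#' For each of `beta_cap`, `beta_TS` and `alpha`, computes the bias
#' (mean of estimate minus truth) and root-mean-square error across
#' subjects; for the transition day it additionally reports the
#' fraction of subjects whose posterior-mean estimate falls within 1 and
#' within 2 days of the true switch day (closed intervals).
#' Non-converged fits are included in all metrics and counted.
#'
#' @param fits A [fit_cohort()] result (or any data frame with
#'   `subject_id`, `beta_cap`, `beta_TS`, `alpha`,
#'   `transition_day_mean`, and optionally `converged`).
#' @param truth A data frame with `subject_id`, `beta_cap`, `beta_TS`,
#'   `alpha`, `transition_day` (e.g. `simulate_population()$truth`).
#' @return An object of class `recovery_report`: a list with `summary`
#'   (tibble of bias and RMSE per parameter), `fraction_within` (named
#'   vector for tolerances 1 and 2 days), `n_subjects`,
#'   `n_nonconverged`, and `config` (echo slot, may be `NULL`).
#' @examples
#' cohort <- simulate_population(simulation_config(n_subjects = 3, seed = 2))
#' fits <- fit_cohort(cohort$training)
#' recover(fits, cohort$truth)
#' @export
recover <- function(fits, truth) {
  unmatched_f <- setdiff(fits$subject_id, truth$subject_id)
  unmatched_t <- setdiff(truth$subject_id, fits$subject_id)
  if (length(unmatched_f) || length(unmatched_t)) {
    abort(paste0(
      "subject ids do not match; unmatched: ",
      paste(head(c(unmatched_f, unmatched_t), 10), collapse = ", ")))
  }
  est <- as_tibble(fits)[c("subject_id", "beta_cap", "beta_TS", "alpha",
                           "transition_day_mean")]
  joined <- left_join(est, as_tibble(truth), by = "subject_id",
                      suffix = c("_est", "_true"))
  metric <- function(e, tr) {
    d <- e - tr
    c(bias = mean(d), rmse = sqrt(mean(d^2)))
  }
  pars <- tibble(
    parameter = c("beta_cap", "beta_TS", "alpha", "transition_day"),
    bias = NA_real_, rmse = NA_real_
  )
  m <- rbind(metric(joined$beta_cap_est, joined$beta_cap_true),
             metric(joined$beta_TS_est, joined$beta_TS_true),
             metric(joined$alpha_est, joined$alpha_true),
             metric(joined$transition_day_mean, joined$transition_day))
  pars$bias <- m[, "bias"]
  pars$rmse <- m[, "rmse"]
  day_err <- abs(joined$transition_day_mean - joined$transition_day)
  fraction_within <- c(`1` = mean(day_err <= 1), `2` = mean(day_err <= 2))
  n_nonconv <- if ("converged" %in% names(fits)) {
    sum(!fits$converged)
  } else 0L
  structure(
    list(summary = pars, fraction_within = fraction_within,
         n_subjects = nrow(joined), n_nonconverged = n_nonconv,
         config = NULL),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> ", x$n_subjects, " subjects (",
      x$n_nonconverged, " non-converged)\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-15s bias % .5f   RMSE %.5f\n",
                s$parameter[i], s$bias[i], s$rmse[i]))
  }
  cat(sprintf("  transition day within 1: %.1f%%, within 2: %.1f%%\n",
              100 * x$fraction_within[["1"]],
              100 * x$fraction_within[["2"]]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.recovery_report <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.recovery_report <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_nonconverged = x$n_nonconverged,
         within_1_day = x$fraction_within[["1"]],
         within_2_days = x$fraction_within[["2"]],
         transition_rmse =
           x$summary$rmse[x$summary$parameter == "transition_day"])
}

#' Pairwise Pearson correlations between two estimate sets
#'
#' Correlates each column of `set_a` with each column of `set_b`
#' (aligned by `subject_id` when present, by row order otherwise),
#' returning Pearson's r and the two-sided p-value for every pair.
#'
#' @param set_a,set_b Data frames of per-subject values, optionally with
#'   a `subject_id` column.
#' @return A tibble with columns `var_a`, `var_b`, `r`, `p_value`.
#' @export
correlate_estimates <- function(set_a, set_b) {
  align <- function(a, b) {
    if ("subject_id" %in% names(a) && "subject_id" %in% names(b)) {
      b <- b[match(a$subject_id, b$subject_id), ]
      a <- a[!is.na(b$subject_id), ]
      b <- b[!is.na(b$subject_id), ]
    }
    list(a = dplyr::select(as_tibble(a), -dplyr::any_of("subject_id")),
         b = dplyr::select(as_tibble(b), -dplyr::any_of("subject_id")))
  }
  al <- align(set_a, set_b)
  if (nrow(al$a) < 3L || nrow(al$a) != nrow(al$b)) {
    abort("need >= 3 aligned rows in both sets.")
  }
  for (nm in names(al$a)) {
    if (sd(al$a[[nm]]) == 0) abort(paste0("zero variance in column ", nm))
  }
  for (nm in names(al$b)) {
    if (sd(al$b[[nm]]) == 0) abort(paste0("zero variance in column ", nm))
  }
  purrr::map_dfr(names(al$a), function(na) {
    purrr::map_dfr(names(al$b), function(nb) {
      ct <- cor.test(al$a[[na]], al$b[[nb]], method = "pearson")
      tibble(var_a = na, var_b = nb,
             r = unname(ct$estimate), p_value = ct$p.value)
    })
  })
}

#' Run the full parameter-recovery simulation study
#'
#' Simulates a cohort from known parameters, fits every subject with the
#' EM-fitted two-phase HMM, and summarises estimation quality:
#' [simulate_population()] then [fit_cohort()] then [recover()].
#' Deterministic for a fixed `seed` in the configuration.
#'
#' @param sim_config A [simulation_config()].
#' @param fit_config Optional named list of [fit_cohort()] arguments
#'   (`max_transition_day` defaults to the simulation configuration's
#'   value, plus `tol`, `max_iter`, `n_restarts`, `seed`).
#' @param keep_fits Keep the full fit cohort in the returned report.
#' @param verbose Forwarded to [fit_cohort()].
#' @return A `recovery_report` whose `config` element echoes both
#'   configurations; when `keep_fits` is `TRUE` the per-subject fits are
#'   attached as `$fits`.
#' @export
run_simulation_study <- function(sim_config, fit_config = list(),
                                 keep_fits = FALSE, verbose = FALSE) {
  cohort <- simulate_population(sim_config)
  fc <- modifyList(
    list(max_transition_day = sim_config$max_transition_day,
         tol = 1e-8, max_iter = 500, n_restarts = 5,
         seed = if (is.null(sim_config$seed)) 1L
                else as.integer(sim_config$seed)),
    fit_config)
  fits <- fit_cohort(cohort$training,
                     max_transition_day = fc$max_transition_day,
                     tol = fc$tol, max_iter = fc$max_iter,
                     n_restarts = fc$n_restarts, seed = fc$seed,
                     verbose = verbose)
  report <- recover(fits, cohort$truth)
  report$config <- list(simulation = unclass(sim_config), fit = fc)
  if (keep_fits) report$fits <- fits
  report
}

#' Serialize a recovery report to JSON
#'
#' @param report A `recovery_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  s <- report$summary
  out <- list(
    bias = as.list(setNames(s$bias, s$parameter)),
    rmse = as.list(setNames(s$rmse, s$parameter)),
    fraction_within = as.list(report$fraction_within),
    n_subjects = report$n_subjects,
    n_nonconverged = report$n_nonconverged,
    package_version = as.character(packageVersion("phasecurve")),
    config = report$config
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
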