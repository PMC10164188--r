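#' Fit the two-phase model to every subject in a training table
#'
#' Splits a long training table into per-subject series and runs
#' [fit_em()] on each. Per-subject failures (e.g. too few observations)
#' never abort the run: the affected row carries the error message and
#' `NA` estimates.
#'
#' @param data A data frame with columns `subject_id`, `session`,
#'   `level` (one row per observed session).
#' @inheritParams fit_em
#' @param verbose Print a progress line every 100 subjects.
#' @return A tibble of class `phase_fit_cohort`, one row per subject:
#'   the parameter estimates (`beta_cap`, `beta_TS`, `alpha`, `tau`,
#'   `sigma`, `delta_TS`), `transition_day_mean`, `transition_day_map`,
#'   `loglik`, `n_iter`, `converged`, `min_trace_step`, `error`
#'   (`NA` unless the subject failed), and list-columns `posterior` and
#'   `trace`.
#' @examples
#' cohort <- simulate_population(simulation_config(n_subjects = 3, seed = 1))
#' fits <- fit_cohort(cohort$training)
#' fits[, c("subject_id", "beta_TS", "transition_day_mean")]
#' @export
fit_cohort <- function(data, max_transition_day = 10, tol = 1e-8,
                       max_iter = 500, n_restarts = 5, seed = 1L,
                       sigma_floor = 1e-6, verbose = FALSE) {
  need <- c("subject_id", "session", "level")
  if (!all(need %in% names(data))) {
    abort("`data` must have columns subject_id, session, level.")
  }
  ids <- unique(data$subject_id)
  pieces <- split(data[c("session", "level")], factor(data$subject_id, ids))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub_seed <- (seed + 7919L * i) %% .Machine$integer.max
    fit <- tryCatch(
      fit_em(pieces[[i]], max_transition_day = max_transition_day,
             tol = tol, max_iter = max_iter, n_restarts = n_restarts,
             seed = sub_seed, sigma_floor = sigma_floor),
      error = function(e) conditionMessage(e)
    )
    rows[[i]] <- if (is.character(fit)) {
      tibble(subject_id = as.character(ids[i]),
             beta_cap = NA_real_, beta_TS = NA_real_, alpha = NA_real_,
             tau = NA_real_, sigma = NA_real_, delta_TS = NA_real_,
             transition_day_mean = NA_real_,
             transition_day_map = NA_integer_,
             loglik = NA_real_, n_iter = NA_integer_, converged = FALSE,
             min_trace_step = NA_real_, error = fit,
             posterior = list(NULL), trace = list(NULL))
    } else {
      tibble(subject_id = as.character(ids[i]),
             beta_cap = fit$params$beta_cap, beta_TS = fit$params$beta_TS,
             alpha = fit$params$alpha, tau = fit$params$tau,
             sigma = fit$params$sigma, delta_TS = fit$delta_TS,
             transition_day_mean = fit$transition_day,
             transition_day_map = fit$transition_day_map,
             loglik = fit$loglik, n_iter = fit$n_iter,
             converged = fit$converged,
             min_trace_step = fit$min_trace_step, error = NA_character_,
             posterior = list(fit$posterior), trace = list(fit$trace))
    }
    if (verbose && i %% 100L == 0L) {
      message(sprintf("fitted %d / %d subjects", i, length(ids)))
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("phase_fit_cohort", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.phase_fit <- function(x, ...) {
  tibble(
    term = c("beta_cap", "beta_TS", "alpha", "tau", "sigma", "delta_TS",
             "transition_day"),
    estimate = c(x$params$beta_cap, x$params$beta_TS, x$params$alpha,
                 x$params$tau, x$params$sigma, x$delta_TS,
                 x$transition_day)
  )
}

#' @exportS3Method generics::glance
glance.phase_fit <- function(x, ...) {
  tibble(loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
         transition_day_mean = x$transition_day,
         transition_day_map = x$transition_day_map,
         n_obs = nrow(x$series))
}

#' @exportS3Method generics::tidy
tidy.phase_posterior <- function(x, ...) {
  tibble(day = x$support, trans_prob = x$trans_pmf)
}

#' Plot a fitted two-phase learning curve
#'
#' Shows the observed daily levels, the fitted phase-1 and phase-2 mean
#' lines (each drawn over the days where its posterior phase probability
#' exceeds one half), and the posterior-mean transition day.
#'
#' @param object A `phase_fit` from [fit_em()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.phase_fit <- function(object, ...) {
  s <- object$series
  p <- object$params
  lines <- dplyr::bind_rows(
    tibble(session = s$session,
           level = predict_mean(p, s$session, 1), phase = "phase 1",
           keep = object$posterior$phase1_prob > 0.5),
    tibble(session = s$session,
           level = predict_mean(p, s$session, 2), phase = "phase 2",
           keep = object$posterior$phase2_prob >= 0.5)
  )
  ggplot2::ggplot(s, ggplot2::aes(x = .data$session, y = .data$level)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_line(
      data = dplyr::filter(lines, .data$keep),
      ggplot2::aes(colour = .data$phase), linewidth = 0.8
    ) +
    ggplot2::geom_vline(xintercept = object$transition_day,
                        linetype = "dashed") +
    ggplot2::labs(x = "training day", y = "level",
                  colour = NULL,
                  title = "Two-phase learning-curve fit") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of estimated transition days in a cohort
#'
#' @param object A `phase_fit_cohort` from [fit_cohort()].
#' @param ... Unused.
#' @return A ggplot object (density of posterior-mean transition days).
#' @exportS3Method ggplot2::autoplot
autoplot.phase_fit_cohort <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), !is.na(.data$transition_day_mean))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$transition_day_mean)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::labs(x = "estimated transition day (posterior mean)",
                  y = "density",
                  title = "Transition-day distribution") +
    ggplot2::theme_minimal()
}

#' Write per-subject fit results to CSV
#'
#' Writes the flat columns of a [fit_cohort()] result (list-columns are
#' dropped) in a stable column order.
#'
#' @param fits A `phase_fit_cohort` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fits_csv <- function(fits, path) {
  cols <- c("subject_id", "beta_cap", "beta_TS", "alpha", "tau", "sigma",
            "delta_TS", "transition_day_mean", "transition_day_map",
            "loglik", "n_iter", "converged", "error")
  readr::write_csv(as_tibble(fits)[intersect(cols, names(fits))], path)
  invisible(path)
}
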