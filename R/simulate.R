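#' Configuration for the synthetic training cohort
#'
#' Defines the generative conditions for simulated subjects: piecewise
#' linear trajectories whose parameters are drawn from uniform
#' distributions, with a known integer switch day and additive Gaussian
#' noise. Defaults reproduce the validation cohort used throughout the
#' package: 1000 subjects, 22 unit-spaced sessions,
#' `alpha ~ U(2, 4)`, `beta_TS ~ U(0.8, 1.6)`, `beta_cap ~ U(0.01, 0.1)`,
#' integer true transition day uniform on `{1..10}`, constant noise
#' standard deviation 0.4 levels.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param n_days Number of daily observations per subject.
#' @param alpha_range,beta_TS_range,beta_cap_range Uniform sampling
#'   bounds `c(low, high)` for the initial level and the two improvement
#'   rates.
#' @param transition_day_range Integer bounds `c(low, high)` for the true
#'   switch day (`high < n_days`).
#' @param noise_sd Noise standard deviation: a scalar or a length
#'   `n_days` per-day vector (levels, `>= 0`).
#' @param max_transition_day Fitting constraint to pass downstream.
#' @param seed Integer RNG seed (or `NULL` to use the current RNG state).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 1000, n_days = 22,
                              alpha_range = c(2, 4),
                              beta_TS_range = c(0.8, 1.6),
                              beta_cap_range = c(0.01, 0.1),
                              transition_day_range = c(1L, 10L),
                              noise_sd = 0.4,
                              max_transition_day = 10,
                              seed = NULL) {
  stopifnot(n_subjects >= 0, n_days >= 4)
  for (r in list(alpha_range, beta_TS_range, beta_cap_range,
                 transition_day_range)) {
    if (length(r) != 2L || r[1] > r[2]) {
      abort("ranges must be c(low, high) with low <= high.")
    }
  }
  if (transition_day_range[2] >= n_days) {
    abort("transition_day_range high must be < n_days.")
  }
  if (any(noise_sd < 0) ||
      !length(noise_sd) %in% c(1L, as.integer(n_days))) {
    abort("`noise_sd` must be >= 0, scalar or one value per day.")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_days = as.integer(n_days),
         alpha_range = alpha_range, beta_TS_range = beta_TS_range,
         beta_cap_range = beta_cap_range,
         transition_day_range = as.integer(transition_day_range),
         noise_sd = noise_sd, max_transition_day = max_transition_day,
         seed = seed),
    class = "simulation_config"
  )
}

draw_cohort <- function(config) {
  n <- config$n_subjects
  days <- seq_len(config$n_days)
  sd_day <- rep(config$noise_sd, length.out = config$n_days)
  truth <- tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    alpha = runif(n, config$alpha_range[1], config$alpha_range[2]),
    beta_TS = runif(n, config$beta_TS_range[1], config$beta_TS_range[2]),
    beta_cap = runif(n, config$beta_cap_range[1], config$beta_cap_range[2]),
    transition_day = {
      days_pool <- seq.int(config$transition_day_range[1],
                           config$transition_day_range[2])
      days_pool[sample.int(length(days_pool), n, replace = TRUE)]
    }
  )
  if (n == 0L) {
    return(list(training = tibble(subject_id = character(),
                                  session = integer(), level = double()),
                truth = truth))
  }
  training <- purrr::map_dfr(seq_len(n), function(i) {
    tr <- truth[i, ]
    mu <- ifelse(days <= tr$transition_day,
                 (tr$beta_cap + tr$beta_TS) * days + tr$alpha,
                 tr$beta_cap * days + tr$beta_TS * tr$transition_day +
                   tr$alpha)
    tibble(subject_id = tr$subject_id, session = days,
           level = mu + rnorm(length(days), 0, sd_day))
  })
  list(training = training, truth = truth)
}

#' Simulate a cohort of training trajectories with known truth
#'
#' Draws each subject's parameters from the configured uniform
#' distributions and an integer switch day, builds the piecewise-linear
#' mean trajectory — continuous at the switch, so the phase-2 offset is
#' `beta_TS * transition_day` — and adds zero-mean Gaussian noise.
#'
#' @param config A [simulation_config()].
#' @return An object of class `sim_cohort`: a list with `training`
#'   (tibble `subject_id`, `session`, `level`), `truth` (tibble
#'   `subject_id`, `alpha`, `beta_TS`, `beta_cap`, `transition_day`),
#'   and the `config`.
#' @examples
#' cohort <- simulate_population(simulation_config(n_subjects = 2, seed = 1))
#' head(cohort$training)
#' @export
simulate_population <- function(config) {
  out <- if (is.null(config$seed)) {
    draw_cohort(config)
  } else {
    withr::with_seed(as.integer(config$seed), draw_cohort(config))
  }
  structure(c(out, list(config = config)), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", x$config$n_subjects, " subjects x ",
      x$config$n_days, " days (seed ",
      if (is.null(x$config$seed)) "none" else x$config$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Simulate a single subject
#'
#' Convenience wrapper over [simulate_population()] for one subject.
#'
#' @param config A [simulation_config()] (its `n_subjects` is ignored).
#' @return A list with `series` (tibble `session`, `level`), `truth`
#'   (one-row tibble), and `config`.
#' @export
simulate_subject <- function(config) {
  config$n_subjects <- 1L
  cohort <- simulate_population(config)
  list(series = cohort$training[c("session", "level")],
       truth = cohort$truth, config = config)
}

#' Configuration for the synthetic transfer-test panel
#'
#' The panel generator emulates the latent structure of the transfer
#' battery: a single capacity factor, linear in session, loading on all
#' four tasks, plus a task-specific step gain on the trained task (Grid)
#' that appears between the first and second test sessions and then
#' stays. The Grid loading defaults to 1.28 and the three transfer-task
#' loadings share the remainder so the four loadings sum to 4; the three
#' transfer-task intercepts sum to 0.
#'
#' @param n_subjects Number of subjects.
#' @param loading_grid Factor loading of the trained task.
#' @param loadings_transfer Length-3 loadings for OOO, FI, Math; must
#'   satisfy `loading_grid + sum(loadings_transfer) == 4`.
#' @param intercepts_transfer Length-3 intercepts for OOO, FI, Math,
#'   summing to 0. The Grid intercept is 0.
#' @param cap_intercept_mean,cap_intercept_sd Normal distribution of the
#'   subject-level capacity at the first test session.
#' @param cap_slope_mean,cap_slope_sd Normal distribution of the
#'   per-session capacity slope.
#' @param ts_step_mean,ts_step_sd Normal distribution of the Grid-only
#'   task-specific step gain.
#' @param resid_sd Residual noise standard deviation per cell.
#' @param missing_rate Probability that a transfer-task cell (OOO, FI,
#'   Math; 15 cells per subject) is set missing.
#' @param seed Integer RNG seed (or `NULL`).
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(n_subjects = 500, loading_grid = 1.28,
                         loadings_transfer = rep((4 - 1.28) / 3, 3),
                         intercepts_transfer = c(0, 0, 0),
                         cap_intercept_mean = 5, cap_intercept_sd = 1,
                         cap_slope_mean = 0.25, cap_slope_sd = 0.1,
                         ts_step_mean = 1, ts_step_sd = 0.3,
                         resid_sd = 0.5, missing_rate = 0, seed = NULL) {
  if (abs(loading_grid + sum(loadings_transfer) - 4) > 1e-8) {
    abort("the four factor loadings must sum to 4.")
  }
  if (abs(sum(intercepts_transfer)) > 1e-8) {
    abort("the three transfer-task intercepts must sum to 0.")
  }
  stopifnot(resid_sd >= 0, missing_rate >= 0, missing_rate <= 1)
  structure(
    list(n_subjects = as.integer(n_subjects), loading_grid = loading_grid,
         loadings_transfer = loadings_transfer,
         intercepts_transfer = intercepts_transfer,
         cap_intercept_mean = cap_intercept_mean,
         cap_intercept_sd = cap_intercept_sd,
         cap_slope_mean = cap_slope_mean, cap_slope_sd = cap_slope_sd,
         ts_step_mean = ts_step_mean, ts_step_sd = ts_step_sd,
         resid_sd = resid_sd, missing_rate = missing_rate, seed = seed),
    class = "panel_config"
  )
}

transfer_tasks <- c("OOO", "FI", "Math")
panel_tasks <- c("Grid", "OOO", "FI", "Math")

draw_panel <- function(config) {
  n <- config$n_subjects
  loadings <- setNames(c(config$loading_grid, config$loadings_transfer),
                       panel_tasks)
  intercepts <- setNames(c(0, config$intercepts_transfer), panel_tasks)
  truth <- tibble(
    subject_id = sprintf("P%04d", seq_len(n)),
    cap_intercept = rnorm(n, config$cap_intercept_mean,
                          config$cap_intercept_sd),
    cap_slope = rnorm(n, config$cap_slope_mean, config$cap_slope_sd),
    ts_step = rnorm(n, config$ts_step_mean, config$ts_step_sd)
  )
  grid <- tidyr::expand_grid(subject_id = truth$subject_id,
                             task = panel_tasks, session = 1:5)
  panel <- grid %>%
    left_join(truth, by = "subject_id") %>%
    mutate(
      cap = .data$cap_intercept + .data$cap_slope * (.data$session - 1),
      score = unname(loadings[.data$task]) * .data$cap +
        unname(intercepts[.data$task]) +
        .data$ts_step * (.data$task == "Grid") * (.data$session >= 2) +
        rnorm(dplyr::n(), 0, config$resid_sd)
    ) %>%
    select("subject_id", "task", "session", "score")
  if (config$missing_rate > 0) {
    hit <- panel$task %in% transfer_tasks &
      runif(nrow(panel)) < config$missing_rate
    panel$score[hit] <- NA_real_
  }
  list(panel = panel, truth = truth)
}

#' Simulate a transfer-test panel with known latent truth
#'
#' Generates scores for the four tasks across the five test sessions as
#' `loading_task * Cap_i(session) + intercept_task +
#' TS_i * [task == Grid] * [session >= 2] + noise`, with the capacity
#' `Cap_i` linear in session. Optionally injects missingness into the
#' transfer-task cells.
#'
#' @param config A [panel_config()].
#' @return A list of class `sim_panel` with `panel` (long tibble
#'   `subject_id`, `task`, `session`, `score`; `NA` score = missing),
#'   `truth` (per-subject latent values) and `config`.
#' @export
simulate_transfer_panel <- function(config) {
  out <- if (is.null(config$seed)) {
    draw_panel(config)
  } else {
    withr::with_seed(as.integer(config$seed), draw_panel(config))
  }
  structure(c(out, list(config = config)), class = "sim_panel")
}
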