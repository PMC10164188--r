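# Core machinery for the two-phase piecewise-linear HMM.
#
# Internals operate on plain numeric vectors t (session days) and y
# (levels). The hidden state is the index k of the last day generated by
# phase 1; k carries the geometric transition weight (1 - tau)^k * tau,
# restricted to the allowed support 1..min(N - 1, max_transition_day).

series_vectors <- function(series) {
  if (is.data.frame(series)) {
    need <- c("session", "level")
    if (!all(need %in% names(series))) {
      abort("`series` must have columns `session` and `level`.")
    }
    if ("subject_id" %in% names(series) &&
        length(unique(series$subject_id)) > 1L) {
      abort("`series` contains more than one subject; use fit_cohort().")
    }
    o <- order(series$session)
    t <- as.numeric(series$session[o])
    y <- as.numeric(series$level[o])
  } else if (is.numeric(series)) {
    y <- as.numeric(series)
    t <- seq_along(y)
  } else {
    abort("`series` must be a data frame or a numeric vector.")
  }
  if (anyDuplicated(t)) abort("duplicate session indices in series.")
  if (any(!is.finite(y))) abort("levels must be finite.")
  if (length(y) < 2L) abort("a series needs at least 2 observations.")
  list(t = t, y = y)
}

support_size <- function(t, max_transition_day) {
  n <- length(t)
  K <- sum(t[seq_len(n - 1L)] <= max_transition_day)
  if (K < 1L) {
    abort("no admissible transition day: check `max_transition_day`.")
  }
  K
}

# log joint weight of each candidate last-phase-1 day k = 1..K
log_weights <- function(par, t, y, K) {
  mu1 <- (par$beta_cap + par$beta_TS) * t + par$alpha
  mu2 <- par$beta_cap * t + par$beta_TS / par$tau + par$alpha
  l1 <- dnorm(y, mu1, par$sigma, log = TRUE)
  l2 <- dnorm(y, mu2, par$sigma, log = TRUE)
  c1 <- cumsum(l1)
  s2 <- rev(cumsum(rev(l2)))            # s2[i] = sum_{t >= i} l2
  k <- seq_len(K)
  k * log1p(-par$tau) + log(par$tau) + c1[k] + c(s2[-1], 0)[k]
}

obs_loglik <- function(par, t, y, K) logsumexp(log_weights(par, t, y, K))

e_quantities <- function(par, t, y, K) {
  lw <- log_weights(par, t, y, K)
  ll <- logsumexp(lw)
  if (!is.finite(ll)) abort("all transition weights underflowed.")
  pmf <- exp(lw - ll)
  pmf <- pmf / sum(pmf)
  n <- length(t)
  # P(phase 1 at day index i) = sum_{k >= i} pmf[k]
  w1 <- pmin(pmax(c(rev(cumsum(rev(pmf))), rep(0, n - K)), 0), 1)
  list(pmf = pmf, w1 = w1, Ek = sum(seq_len(K) * pmf), loglik = ll)
}

# expected complete-data log likelihood under phase weights w1 / E[k]
q_value <- function(par, t, y, w1, Ek) {
  mu1 <- (par$beta_cap + par$beta_TS) * t + par$alpha
  mu2 <- par$beta_cap * t + par$beta_TS / par$tau + par$alpha
  l1 <- dnorm(y, mu1, par$sigma, log = TRUE)
  l2 <- dnorm(y, mu2, par$sigma, log = TRUE)
  Ek * log1p(-par$tau) + log(par$tau) + sum(w1 * l1 + (1 - w1) * l2)
}

# weighted least squares for (beta_cap, beta_TS, alpha) given tau:
# phase-1 rows  y ~ (b + B) t + a   with weight w1
# phase-2 rows  y ~ b t + B / tau + a with weight 1 - w1
wls_linear <- function(t, y, w1, tau) {
  X <- cbind(c(t, t), c(t, rep(1 / tau, length(t))), 1)
  w <- c(w1, 1 - w1)
  yy <- c(y, y)
  XtW <- t.default(X * w)
  cf <- tryCatch(drop(solve(XtW %*% X, XtW %*% yy)),
                 error = function(e) NULL)
  if (is.null(cf)) {
    cf <- lm.wfit(X, yy, w)$coefficients  # rank-deficient fallback
    cf[is.na(cf)] <- 0
  }
  cf
}

sigma_update <- function(par, t, y, w1, floor) {
  r1 <- y - ((par$beta_cap + par$beta_TS) * t + par$alpha)
  r2 <- y - (par$beta_cap * t + par$beta_TS / par$tau + par$alpha)
  max(sqrt(sum(w1 * r1^2 + (1 - w1) * r2^2) / length(y)), floor)
}

# Maximizes the expected complete-data log likelihood by profiling over
# tau: for each candidate tau the linear coefficients have an exact
# weighted least-squares solution and sigma a closed form, so the whole
# M-step reduces to a 1-d search (tau enters both the geometric prior
# and the phase-2 offset beta_TS / tau, so it has no closed form). The
# objective at the returned parameters never falls below its value at
# the input (generalized EM guard).
mstep_core <- function(par, t, y, w1, Ek, sigma_floor = 1e-6,
                       n_cycles = 1L) {
  at_tau <- function(tau) {
    cf <- wls_linear(t, y, w1, tau)
    cand <- list(beta_cap = cf[[1]], beta_TS = cf[[2]], alpha = cf[[3]],
                 tau = tau, sigma = par$sigma)
    cand$sigma <- sigma_update(cand, t, y, w1, sigma_floor)
    cand
  }
  op <- optimize(function(tau) q_value(at_tau(tau), t, y, w1, Ek),
                 c(1e-6, 1 - 1e-9), maximum = TRUE, tol = 1e-10)
  cand <- at_tau(op$maximum)
  if (q_value(cand, t, y, w1, Ek) >= q_value(par, t, y, w1, Ek)) {
    cand
  } else {
    par
  }
}

run_em <- function(par, t, y, K, tol, max_iter, sigma_floor) {
  trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  repeat {
    es <- e_quantities(par, t, y, K)
    trace <- c(trace, es$loglik)
    if (length(trace) > 1L &&
        abs(trace[length(trace)] - trace[length(trace) - 1L]) < tol) {
      converged <- TRUE
      break
    }
    if (n_iter >= max_iter) break
    par <- mstep_core(par, t, y, es$w1, es$Ek, sigma_floor)
    n_iter <- n_iter + 1L
  }
  list(par = par, loglik = trace[length(trace)], trace = trace,
       n_iter = n_iter, converged = converged)
}

as_par_list <- function(v) {
  list(beta_cap = v[[1]], beta_TS = v[[2]], alpha = v[[3]],
       tau = v[[4]], sigma = v[[5]])
}

ls_slope <- function(t, y) {
  if (length(t) < 2L || sd(t) == 0) return(0)
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

heuristic_init <- function(t, y, sigma_floor) {
  n <- length(y)
  half <- seq.int(floor(n / 2) + 1L, n)
  b0 <- ls_slope(t[half], y[half])
  s1 <- ls_slope(head(t, 5L), head(y, 5L))
  r <- y - (mean(y) + ls_slope(t, y) * (t - mean(t)))
  list(beta_cap = b0,
       beta_TS = max(s1 - b0, 0),
       alpha = y[[1]],
       tau = 0.5,
       sigma = max(sd(r), 1e-3))
}

# best hard-segmentation fit over all candidate switch days, used as one
# of the EM starting points
segmentation_init <- function(t, y, K, init, sigma_floor) {
  n <- length(y)
  best <- NULL
  best_ll <- -Inf
  for (k in seq_len(K)) {
    w1 <- as.numeric(seq_len(n) <= k)
    cand <- mstep_core(init, t, y, w1, Ek = k, sigma_floor = sigma_floor)
    ll <- obs_loglik(cand, t, y, K)
    if (ll > best_ll) {
      best_ll <- ll
      best <- cand
    }
  }
  best
}

polish_obs <- function(par, t, y, K, sigma_floor) {
  tau0 <- min(max(par$tau, 1e-6), 1 - 1e-9)
  x0 <- c(par$beta_cap, par$beta_TS, par$alpha,
          stats::qlogis(tau0), log(max(par$sigma, sigma_floor)))
  fn <- function(x) {
    p <- list(beta_cap = x[1], beta_TS = x[2], alpha = x[3],
              tau = min(max(stats::plogis(x[4]), 1e-6), 1 - 1e-9),
              sigma = max(exp(x[5]), sigma_floor))
    ll <- obs_loglik(p, t, y, K)
    if (!is.finite(ll)) -1e300 else ll
  }
  op <- tryCatch(
    optim(x0, fn, method = "Nelder-Mead",
          control = list(fnscale = -1, maxit = 1000, reltol = 1e-13)),
    error = function(e) NULL
  )
  if (is.null(op) || op$value <= obs_loglik(par, t, y, K)) return(par)
  list(beta_cap = op$par[1], beta_TS = op$par[2], alpha = op$par[3],
       tau = min(max(stats::plogis(op$par[4]), 1e-6), 1 - 1e-9),
       sigma = max(exp(op$par[5]), sigma_floor))
}

#' Posterior over the transition day and per-day phase probabilities
#'
#' For a given parameter set, computes the posterior probability mass
#' function of the hidden transition day (the last day generated by
#' phase 1) over the allowed support `1..min(N - 1, max_transition_day)`,
#' and the derived per-day probabilities of being in phase 1 or phase 2.
#' The joint weight of candidate day `k` is the geometric transition
#' weight `(1 - tau)^k * tau` times the phase-1 Gaussian likelihood of
#' the first `k` observations and the phase-2 likelihood of the rest;
#' all computation is in log space. `tau` must be below 1: at `tau = 1`
#' every candidate day carries the factor `1 - tau = 0`.
#'
#' @param params An [hmm_params] object (or compatible list).
#' @param series A data frame with columns `session` and `level` for one
#'   subject, or a numeric vector of levels at days `1..N`.
#' @param max_transition_day Latest allowed transition day (default 10).
#' @return An object of class `phase_posterior`: a list with elements
#'   `support` (candidate days), `trans_pmf` (posterior mass, sums to 1),
#'   `days`, `phase1_prob`, `phase2_prob` (per-day, complementary), and
#'   `loglik` (observed-data log likelihood at `params`).
#' @export
transition_pmf <- function(params, series, max_transition_day = 10) {
  if (params$tau >= 1) abort("`tau` must be < 1 to form the posterior.")
  sv <- series_vectors(series)
  if (length(sv$y) < 3L) abort("series must have at least 3 observations.")
  K <- support_size(sv$t, max_transition_day)
  es <- e_quantities(params, sv$t, sv$y, K)
  structure(
    list(support = seq_len(K), trans_pmf = es$pmf, days = sv$t,
         phase1_prob = es$w1, phase2_prob = 1 - es$w1,
         loglik = es$loglik),
    class = "phase_posterior"
  )
}

#' @export
print.phase_posterior <- function(x, ...) {
  cat("<phase_posterior> support 1..", max(x$support), "\n", sep = "")
  est <- estimate_transition_day(x)
  cat(sprintf("  transition day: mean %.3f, MAP %d\n",
              est$mean_day, est$map_day))
  invisible(x)
}

#' Expectation step of the EM algorithm
#'
#' Computes the posterior over the hidden transition day at the current
#' parameters; a thin wrapper over [transition_pmf()].
#'
#' @inheritParams transition_pmf
#' @return A `phase_posterior` object.
#' @export
e_step <- function(params, series, max_transition_day = 10) {
  transition_pmf(params, series, max_transition_day)
}

#' Maximization step of the EM algorithm
#'
#' Maximizes the expected complete-data log likelihood over the five
#' model parameters, holding the transition-day posterior fixed. The
#' problem is profiled over `tau`: for a given `tau` the linear
#' coefficients have an exact weighted least-squares solution and the
#' noise standard deviation a closed form, so the maximization reduces
#' to a one-dimensional search over `tau`. The objective at the returned
#' parameters is never below its value at `current`.
#'
#' @param series As in [transition_pmf()].
#' @param posterior A `phase_posterior` from [e_step()].
#' @param current Current [hmm_params].
#' @param sigma_floor Lower bound for the noise standard deviation.
#' @return An [hmm_params] object.
#' @export
m_step <- function(series, posterior, current, sigma_floor = 1e-6) {
  sv <- series_vectors(series)
  K <- length(posterior$support)
  w1 <- posterior$phase1_prob
  Ek <- sum(posterior$support * posterior$trans_pmf)
  out <- mstep_core(as.list(current)[c("beta_cap", "beta_TS", "alpha",
                                       "tau", "sigma")],
                    sv$t, sv$y, w1, Ek, sigma_floor)
  hmm_params(out$beta_cap, out$beta_TS, out$alpha, out$tau, out$sigma)
}

#' Fit the two-phase learning-curve model to one subject
#'
#' Estimates the five model parameters by expectation-maximization:
#' alternating the transition-day posterior ([e_step()]) with parameter
#' updates ([m_step()]) until the observed-data log likelihood changes by
#' less than `tol`. Several starting points are used (a slope-based
#' heuristic, the best hard-segmentation fit over candidate switch days,
#' and jittered copies of the heuristic), the best final likelihood
#' wins, and a final joint numeric polish of the observed-data
#' likelihood is applied. Levels are internally rescaled by their
#' standard deviation for numerical conditioning, so estimates are
#' exactly scale-covariant.
#'
#' @inheritParams transition_pmf
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations per start.
#' @param n_restarts Total number of starting points (>= 1).
#' @param seed Integer seed controlling the jittered restarts.
#' @param sigma_floor Lower bound on the noise standard deviation.
#' @return An object of class `phase_fit`: a list with `params`
#'   ([hmm_params]), `posterior` (`phase_posterior`), `transition_day`
#'   (posterior mean, continuous), `transition_day_map` (posterior mode,
#'   earliest on ties), `delta_TS`, `loglik`, `trace` (log-likelihood
#'   trace of the winning start, non-decreasing), `min_trace_step`
#'   (smallest per-iteration log-likelihood change over all starts),
#'   `n_iter`, `converged`, and the input `series`.
#' @examples
#' sim <- simulate_subject(simulation_config(n_subjects = 1, seed = 7))
#' fit <- fit_em(sim$series)
#' tidy(fit)
#' @export
fit_em <- function(series, max_transition_day = 10, tol = 1e-8,
                   max_iter = 500, n_restarts = 5, seed = 1L,
                   sigma_floor = 1e-6) {
  sv <- series_vectors(series)
  t <- sv$t
  y <- sv$y
  if (length(y) < 4L) abort("fit_em() needs at least 4 observations.")
  K <- support_size(t, max_transition_day)

  s_y <- sd(y)
  if (!is.finite(s_y) || s_y == 0) s_y <- 1
  z <- y / s_y

  init1 <- heuristic_init(t, z, sigma_floor)
  inits <- list(init1)
  if (n_restarts >= 2L) {
    inits <- c(inits, list(segmentation_init(t, z, K, init1, sigma_floor)))
  }
  n_jit <- max(n_restarts - 2L, 0L)
  if (n_jit > 0L) {
    jit <- withr::with_seed(seed, {
      lapply(seq_len(n_jit), function(i) {
        list(beta_cap = init1$beta_cap * exp(rnorm(1, 0, 0.3)),
             beta_TS = max(init1$beta_TS, 0.05) * exp(rnorm(1, 0, 0.3)),
             alpha = init1$alpha + rnorm(1, 0, max(init1$sigma, 0.1)),
             tau = runif(1, 0.05, 0.95),
             sigma = init1$sigma * exp(rnorm(1, 0, 0.3)))
      })
    })
    inits <- c(inits, jit)
  }

  best <- NULL
  min_step <- Inf
  for (ini in inits) {
    run <- run_em(ini, t, z, K, tol, max_iter, sigma_floor)
    if (length(run$trace) > 1L) {
      min_step <- min(min_step, min(diff(run$trace)))
    }
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }

  pol <- polish_obs(best$par, t, z, K, sigma_floor)
  ll_pol <- obs_loglik(pol, t, z, K)
  if (ll_pol > best$loglik) {
    best$par <- pol
    best$trace <- c(best$trace, ll_pol)
    best$loglik <- ll_pol
  }

  par <- best$par
  par <- hmm_params(par$beta_cap * s_y, par$beta_TS * s_y,
                    par$alpha * s_y, par$tau,
                    max(par$sigma * s_y, sigma_floor))
  post <- transition_pmf(par, tibble(session = t, level = y),
                         max_transition_day)
  est <- estimate_transition_day(post)
  structure(
    list(params = par, posterior = post,
         transition_day = est$mean_day,
         transition_day_map = est$map_day,
         delta_TS = delta_TS(par),
         loglik = post$loglik,
         trace = best$trace - length(y) * log(s_y),
         min_trace_step = if (is.finite(min_step)) min_step else 0,
         n_iter = best$n_iter, converged = best$converged,
         series = tibble(session = t, level = y),
         max_transition_day = max_transition_day),
    class = "phase_fit"
  )
}

#' @export
print.phase_fit <- function(x, ...) {
  cat("<phase_fit> ", nrow(x$series), " sessions, loglik ",
      sprintf("%.4f", x$loglik), "\n", sep = "")
  print(x$params)
  cat(sprintf("  transition day: mean %.3f, MAP %d (%s, %d EM iterations)\n",
              x$transition_day, x$transition_day_map,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Point estimates of the transition day from its posterior
#'
#' @param posterior A `phase_posterior` object.
#' @return A list with `mean_day` (posterior mean, continuous) and
#'   `map_day` (posterior mode; the earliest day on ties).
#' @export
estimate_transition_day <- function(posterior) {
  p <- posterior$trans_pmf
  k <- posterior$support
  list(mean_day = sum(k * p), map_day = as.integer(k[which.max(p)]))
}

#' Flag subjects with an extreme capacity slope
#'
#' Flags subjects whose fitted `beta_cap` exceeds `multiplier` times the
#' standard deviation of `beta_cap` across the whole cohort (computed in
#' one pass, including the candidates). With zero cohort standard
#' deviation nobody is flagged.
#'
#' @param fits A data frame with columns `subject_id` and `beta_cap`
#'   (e.g. from [fit_cohort()]).
#' @param multiplier Threshold multiplier (default 10).
#' @return Character vector of flagged subject ids (possibly empty).
#' @export
flag_outliers <- function(fits, multiplier = 10) {
  if (!all(c("subject_id", "beta_cap") %in% names(fits))) {
    abort("`fits` must have columns `subject_id` and `beta_cap`.")
  }
  b <- fits$beta_cap
  if (sum(is.finite(b)) < 2L) abort("need at least 2 fitted subjects.")
  s <- sd(b, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(character(0))
  as.character(fits$subject_id[!is.na(b) & b > multiplier * s])
}
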