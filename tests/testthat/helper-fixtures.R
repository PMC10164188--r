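# Shared fixtures and independent oracles used across test files.

# deterministic piecewise series: switch after day k (continuous there)
make_piecewise <- function(n_days, beta_cap, beta_TS, alpha, k,
                           noise_sd = 0, seed = NULL) {
  t <- seq_len(n_days)
  mu <- ifelse(t <= k, (beta_cap + beta_TS) * t + alpha,
               beta_cap * t + beta_TS * k + alpha)
  y <- if (noise_sd > 0) {
    withr::with_seed(seed, mu + rnorm(n_days, 0, noise_sd))
  } else mu
  tibble::tibble(session = t, level = y)
}

# Brute-force transition-day posterior: direct per-candidate products of
# normal densities, no log-space tricks (independent of the package path).
brute_pmf <- function(params, y, max_transition_day = 10) {
  t <- seq_along(y)
  K <- min(length(y) - 1, max_transition_day)
  w <- numeric(K)
  for (k in seq_len(K)) {
    prior <- (1 - params$tau)^k * params$tau
    lik <- 1
    for (i in t) {
      mu <- if (i <= k) {
        (params$beta_cap + params$beta_TS) * i + params$alpha
      } else {
        params$beta_cap * i + params$beta_TS / params$tau + params$alpha
      }
      lik <- lik * dnorm(y[i], mu, params$sigma)
    }
    w[k] <- prior * lik
  }
  w / sum(w)
}

# Hard-segmentation oracle: for each candidate switch day k, maximise the
# complete-data likelihood of that segmentation (profile over tau with an
# inner exact weighted least-squares fit of the linear coefficients and
# the closed-form sigma), then score the resulting parameter set by the
# observed-data (mixture) log likelihood. Returns the best value over k.
oracle_loglik <- function(y, max_transition_day = 10,
                          sigma_floor = 1e-6) {
  t <- seq_along(y)
  n <- length(y)
  K <- min(n - 1, max_transition_day)

  mixture_ll <- function(p) {
    total <- -Inf
    for (k in seq_len(K)) {
      mu <- ifelse(t <= k, (p$beta_cap + p$beta_TS) * t + p$alpha,
                   p$beta_cap * t + p$beta_TS / p$tau + p$alpha)
      lw <- k * log(1 - p$tau + (p$tau == 1) * 1e-300) +
        log(p$tau) + sum(dnorm(y, mu, p$sigma, log = TRUE))
      total <- max(total, lw) + log1p(exp(min(total, lw) - max(total, lw)))
    }
    total
  }

  fit_for_k_tau <- function(k, tau) {
    in1 <- t <= k
    X <- cbind(t, ifelse(in1, t, 1 / tau), 1)
    cf <- qr.coef(qr(X), y)
    cf[is.na(cf)] <- 0
    mu <- X %*% cf
    sigma <- max(sqrt(mean((y - mu)^2)), sigma_floor)
    list(beta_cap = cf[[1]], beta_TS = cf[[2]], alpha = cf[[3]],
         tau = tau, sigma = sigma)
  }

  hard_ll <- function(k, tau) {
    p <- fit_for_k_tau(k, tau)
    mu <- ifelse(t <= k, (p$beta_cap + p$beta_TS) * t + p$alpha,
                 p$beta_cap * t + p$beta_TS / p$tau + p$alpha)
    k * log1p(-min(tau, 1 - 1e-12)) + log(tau) +
      sum(dnorm(y, mu, p$sigma, log = TRUE))
  }

  best <- -Inf
  for (k in seq_len(K)) {
    op <- optimize(function(tau) hard_ll(k, tau), c(1e-6, 1 - 1e-9),
                   maximum = TRUE, tol = 1e-10)
    p <- fit_for_k_tau(k, op$maximum)
    best <- max(best, mixture_ll(p))
  }
  best
}

# small transfer panel in long form from a wide score matrix
# (rows = subjects, 20 columns task_session); NA = missing
panel_from_matrix <- function(X, ids = sprintf("P%02d", seq_len(nrow(X)))) {
  tasks <- c("Grid", "OOO", "FI", "Math")
  grid <- expand.grid(session = 1:5, task = tasks,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(X)), function(i) {
    data.frame(subject_id = ids[i], task = grid$task,
               session = grid$session, score = as.numeric(X[i, ]))
  }))
  tibble::as_tibble(out[c("subject_id", "task", "session", "score")])
}
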