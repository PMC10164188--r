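# EM fitting: M-step properties, noiseless identifiability, oracle
# equivalence on small series, scale covariance.

# independent expected complete-data log likelihood, by direct summation
q_oracle <- function(p, y, pmf) {
  t <- seq_along(y)
  K <- length(pmf)
  total <- 0
  for (k in seq_len(K)) {
    prior <- k * log(1 - p$tau) + log(p$tau)
    ll <- sum(sapply(t, function(i) {
      mu <- if (i <= k) (p$beta_cap + p$beta_TS) * i + p$alpha
      else p$beta_cap * i + p$beta_TS / p$tau + p$alpha
      dnorm(y[i], mu, p$sigma, log = TRUE)
    }))
    total <- total + pmf[k] * (prior + ll)
  }
  total
}

test_that("m_step with a point-mass posterior interpolates noiseless model data", {
  gen <- hmm_params(0.05, 1, 3, tau = 0.4, sigma = 1)
  t <- 1:15
  k <- 5
  y <- ifelse(t <= k, predict_mean(gen, t, 1), predict_mean(gen, t, 2))
  series <- tibble::tibble(session = t, level = y)
  post <- structure(
    list(support = 1:10,
         trans_pmf = as.numeric(1:10 == k),
         phase1_prob = c(as.numeric(t <= k)),
         phase2_prob = c(as.numeric(t > k))),
    class = "phase_posterior"
  )
  out <- m_step(series, post, hmm_params(0.02, 0.8, 2.5, 0.45, 0.5))
  expect_equal(out$beta_cap, 0.05, tolerance = 1e-6)
  expect_equal(out$beta_TS, 1, tolerance = 1e-6)
  expect_equal(out$alpha, 3, tolerance = 1e-6)
  expect_equal(out$tau, 0.4, tolerance = 1e-4)
  expect_equal(out$sigma, 1e-6)   # floored
})

test_that("m_step beats random probes and never decreases the objective", {
  withr::local_seed(21)
  y <- make_piecewise(10, 0.05, 1, 3, 4, noise_sd = 0.3, seed = 22)$level
  series <- tibble::tibble(session = 1:10, level = y)
  cur <- hmm_params(0.04, 0.9, 3.1, 0.5, 0.4)
  post <- e_step(cur, series)
  out <- m_step(series, post, cur)
  q_out <- q_oracle(out, y, post$trans_pmf)
  expect_gte(q_out, q_oracle(cur, y, post$trans_pmf))
  for (i in 1:100) {
    probe <- list(beta_cap = out$beta_cap + rnorm(1, 0, 0.02),
                  beta_TS = out$beta_TS + rnorm(1, 0, 0.05),
                  alpha = out$alpha + rnorm(1, 0, 0.05),
                  tau = min(max(out$tau + rnorm(1, 0, 0.05), 1e-4), 1),
                  sigma = out$sigma * exp(rnorm(1, 0, 0.1)))
    expect_gte(q_out, q_oracle(probe, y, post$trans_pmf) - 1e-10)
  }
})

test_that("returned sigma^2 is the posterior-weighted mean squared residual", {
  y <- make_piecewise(12, 0.06, 1.1, 2.8, 5, noise_sd = 0.4, seed = 9)$level
  series <- tibble::tibble(session = 1:12, level = y)
  cur <- hmm_params(0.05, 1, 3, 0.4, 0.5)
  post <- e_step(cur, series)
  out <- m_step(series, post, cur)
  t <- 1:12
  w1 <- post$phase1_prob
  r1 <- y - ((out$beta_cap + out$beta_TS) * t + out$alpha)
  r2 <- y - (out$beta_cap * t + out$beta_TS / out$tau + out$alpha)
  expect_equal(out$sigma^2, sum(w1 * r1^2 + (1 - w1) * r2^2) / 12,
               tolerance = 1e-8)
})

test_that("noiseless series are fitted exactly, up to the switch-day ambiguity", {
  series <- make_piecewise(22, beta_cap = 0.05, beta_TS = 1, alpha = 3,
                           k = 4)
  fit <- fit_em(series)
  expect_equal(fit$params$beta_cap, 0.05, tolerance = 1e-6)
  expect_equal(fit$params$beta_TS, 1, tolerance = 1e-6)
  expect_equal(fit$params$alpha, 3, tolerance = 1e-6)
  # continuous data: days 3 and 4 explain the switch equally well
  expect_true(fit$transition_day_map %in% c(3L, 4L))
  expect_lt(abs(fit$transition_day - 4), 1)
  expect_true(fit$converged)
})

test_that("EM reaches the exhaustive-segmentation oracle likelihood", {
  withr::local_seed(33)
  for (i in 1:12) {
    n <- sample(5:8, 1)
    y <- if (i %% 2 == 0) {
      runif(n, 2, 8)
    } else {
      make_piecewise(n, runif(1, 0, 0.1), runif(1, 0.5, 1.5),
                     runif(1, 2, 4), sample(2:(n - 2), 1),
                     noise_sd = 0.3, seed = 100 + i)$level
    }
    fit <- fit_em(tibble::tibble(session = 1:n, level = y))
    expect_gte(fit$loglik, oracle_loglik(y) - 1e-6)
    expect_gte(fit$min_trace_step, -1e-8)
  }
})

test_that("estimates are scale covariant and the posterior scale free", {
  series <- make_piecewise(22, 0.06, 1.2, 3.2, 5, noise_sd = 0.4,
                           seed = 14)
  f1 <- fit_em(series)
  c_ <- 2.5
  f2 <- fit_em(dplyr::mutate(series, level = level * c_))
  for (nm in c("beta_cap", "beta_TS", "alpha", "sigma")) {
    expect_equal(f2$params[[nm]], c_ * f1$params[[nm]], tolerance = 1e-6)
  }
  expect_equal(f2$params$tau, f1$params$tau, tolerance = 1e-6)
  expect_equal(f2$posterior$trans_pmf, f1$posterior$trans_pmf,
               tolerance = 1e-6)
})

test_that("fitting is invariant to the row order of the series", {
  series <- make_piecewise(15, 0.05, 1, 3, 6, noise_sd = 0.3, seed = 15)
  f1 <- fit_em(series)
  f2 <- fit_em(series[sample(15), ])
  expect_equal(tidy(f2), tidy(f1), tolerance = 1e-12)
})

test_that("fit_em rejects series that are too short", {
  expect_error(fit_em(tibble::tibble(session = 1:3, level = c(1, 2, 3))),
               "at least 4")
})
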