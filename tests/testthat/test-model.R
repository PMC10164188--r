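# model means, emissions, transition-day posterior, derived quantities

fig_params <- hmm_params(beta_cap = 0.013, beta_TS = 0.269,
                         alpha = 5.497, tau = 0.481, sigma = 0.5)

test_that("phase means follow the two-phase piecewise-linear model", {
  expect_equal(predict_mean(fig_params, 0, 1), 5.497)
  expect_equal(predict_mean(fig_params, 3, 1), 5.497 + 0.282 * 3)
  expect_equal(predict_mean(fig_params, 10, 2),
               5.497 + 0.13 + 0.269 / 0.481)
  expect_error(predict_mean(fig_params, 1, 3), "phase")
})

test_that("emission log density is Gaussian around the phase mean", {
  p <- hmm_params(0.05, 1, 3, 0.5, 1)
  peak <- emission_logpdf(p, predict_mean(p, 4, 1), 4, 1)
  expect_equal(peak, -0.5 * log(2 * pi))
  expect_equal(emission_logpdf(p, predict_mean(p, 4, 1) + 1, 4, 1),
               peak - 0.5)
  p2 <- hmm_params(0.05, 1, 3, 0.5, 2)
  expect_equal(emission_logpdf(p2, predict_mean(p2, 4, 1), 4, 1),
               peak - log(2))
  expect_error(emission_logpdf(p, NaN, 4, 1), "finite")
})

test_that("delta_TS is the rate over the transition probability", {
  expect_equal(delta_TS(hmm_params(0, 1, 0, 0.5, 1)), 2)
  expect_equal(delta_TS(hmm_params(0, 0, 0, 0.7, 1)), 0)
  expect_equal(delta_TS(fig_params), 0.269 / 0.481)
  expect_error(delta_TS(list(beta_TS = 1, tau = 0)), "tau")
})

test_that("transition pmf matches brute-force enumeration on a toy series", {
  p <- hmm_params(0.1, 0.8, 2.5, 0.4, 0.6)
  y <- c(3.1, 4.4, 5.0, 5.3, 5.2)
  post <- transition_pmf(p, y)
  expect_equal(post$trans_pmf, brute_pmf(p, y), tolerance = 1e-12)
  expect_equal(sum(post$trans_pmf), 1, tolerance = 1e-10)
})

test_that("posterior concentrates on the true switch day as noise vanishes", {
  # data generated from the model's own phase means (tau != 1/k, so the
  # switch-day observation is NOT on the phase-2 line and day k is the
  # unique exact segmentation)
  k <- 5
  t <- 1:12
  gen <- hmm_params(0.05, 1, 3, tau = 0.4, sigma = 1)
  y <- ifelse(t <= k, predict_mean(gen, t, 1), predict_mean(gen, t, 2))
  mass_at_k <- sapply(c(0.5, 0.1, 0.01), function(sg) {
    p <- hmm_params(0.05, 1, 3, 0.4, sg)
    transition_pmf(p, y)$trans_pmf[k]
  })
  expect_true(all(diff(mass_at_k) > -1e-9))
  expect_gt(mass_at_k[3], 0.999)

  # for a trajectory continuous at the switch, days k-1 and k explain the
  # data equally well and share all the mass, split by the prior
  s <- make_piecewise(12, beta_cap = 0.05, beta_TS = 1, alpha = 3, k = 5)
  p <- hmm_params(0.05, 1, 3, 1 / 5, 1e-5)
  post <- transition_pmf(p, s)
  expect_equal(sum(post$trans_pmf[c(4, 5)]), 1, tolerance = 1e-9)
  expect_gt(post$trans_pmf[4], post$trans_pmf[5])
})

test_that("with no task-specific gain the posterior is the geometric prior", {
  p <- hmm_params(0.2, 0, 3, 0.3, 0.5)
  withr::local_seed(5)
  y <- 3 + 0.2 * (1:12) + rnorm(12, 0, 0.5)
  post <- transition_pmf(p, y)
  k <- 1:10
  prior <- (1 - 0.3)^(k - 1) * 0.3
  expect_equal(post$trans_pmf, prior / sum(prior), tolerance = 1e-12)
})

test_that("phase posteriors are complementary and monotone", {
  withr::local_seed(6)
  for (i in 1:10) {
    p <- hmm_params(runif(1, 0, 0.2), runif(1, 0.5, 1.5), runif(1, 2, 4),
                    runif(1, 0.1, 0.9), runif(1, 0.2, 1))
    y <- runif(15, 2, 12)
    post <- transition_pmf(p, y)
    expect_equal(sum(post$trans_pmf), 1, tolerance = 1e-10)
    expect_equal(post$phase1_prob + post$phase2_prob, rep(1, 15),
                 tolerance = 1e-10)
    expect_true(all(diff(post$phase1_prob) <= 1e-12))
    expect_true(all(diff(post$phase2_prob) >= -1e-12))
    expect_equal(post$phase1_prob[1], 1)
  }
})

test_that("transition-day point estimates follow the pmf", {
  mk <- function(pmf) {
    structure(list(support = seq_along(pmf), trans_pmf = pmf),
              class = "phase_posterior")
  }
  expect_equal(estimate_transition_day(mk(c(0, 0, 1, 0))),
               list(mean_day = 3, map_day = 3L))
  est <- estimate_transition_day(mk(rep(0.1, 10)))
  expect_equal(est$mean_day, 5.5)
  expect_equal(est$map_day, 1L)   # earliest on ties
  est2 <- estimate_transition_day(mk(c(0, 0.5, 0.5)))
  expect_equal(est2$mean_day, 2.5)
  expect_equal(est2$map_day, 2L)
})

test_that("outlier flagging uses the one-pass population sd", {
  withr::local_seed(11)
  fits <- tibble::tibble(subject_id = sprintf("s%d", 1:200),
                         beta_cap = c(rnorm(199, 0.05, 0.02), 5))
  flagged <- flag_outliers(fits)
  expect_equal(flagged, "s200")
  # direct recomputation including the candidate
  expect_true(5 > 10 * sd(fits$beta_cap))

  same <- tibble::tibble(subject_id = c("a", "b", "c"),
                         beta_cap = c(0.1, 0.1, 0.1))
  expect_equal(flag_outliers(same), character(0))
})
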