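#' Parameters of the two-phase learning-curve model
#'
#' Bundles the five free parameters of the piecewise-linear hidden Markov
#' model of training improvement. During the first learning phase,
#' performance grows at the combined rate `beta_cap + beta_TS`
#' (capacity plus task-specific improvement); after the hidden switch to
#' the second phase only the capacity rate `beta_cap` remains, and the
#' accumulated task-specific gain enters as the offset
#' `delta_TS = beta_TS / tau`. Observations carry additive Gaussian noise
#' with standard deviation `sigma`, and the per-day probability of
#' switching from phase 1 to phase 2 is `tau` (geometric dwell time;
#' a return to phase 1 is impossible).
#'
#' @param beta_cap Capacity improvement rate (levels/day).
#' @param beta_TS Task-specific improvement rate during phase 1
#'   (levels/day).
#' @param alpha Initial performance level at day 0 (levels).
#' @param tau Per-day phase-1 to phase-2 transition probability, in
#'   `(0, 1]`.
#' @param sigma Emission noise standard deviation (levels), `> 0`.
#'
#' @return An object of class `hmm_params`: a named list with the five
#'   parameters.
#' @examples
#' p <- hmm_params(beta_cap = 0.013, beta_TS = 0.269, alpha = 5.497,
#'                 tau = 0.481, sigma = 0.5)
#' delta_TS(p)
#' @export
hmm_params <- function(beta_cap, beta_TS, alpha, tau, sigma) {
  for (nm in c("beta_cap", "beta_TS", "alpha", "tau", "sigma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(paste0("`", nm, "` must be a single finite number."))
    }
  }
  if (tau <= 0 || tau > 1) abort("`tau` must lie in (0, 1].")
  if (sigma <= 0) abort("`sigma` must be > 0.")
  structure(
    list(beta_cap = beta_cap, beta_TS = beta_TS, alpha = alpha,
         tau = tau, sigma = sigma),
    class = "hmm_params"
  )
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params>\n")
  cat(sprintf("  beta_cap = %.6g  beta_TS = %.6g  alpha = %.6g\n",
              x$beta_cap, x$beta_TS, x$alpha))
  cat(sprintf("  tau = %.6g  sigma = %.6g  (delta_TS = %.6g)\n",
              x$tau, x$sigma, x$beta_TS / x$tau))
  invisible(x)
}

#' Total task-specific gain at the phase switch
#'
#' The expected accumulated task-specific improvement when the model
#' leaves phase 1: the task-specific rate times the expected dwell time
#' `1/tau`, i.e. `beta_TS / tau`.
#'
#' @param params An [hmm_params] object (or any list with `beta_TS` and
#'   `tau`).
#' @return A single number, the task-specific plateau offset (levels).
#' @export
delta_TS <- function(params) {
  if (is.null(params$tau) || params$tau <= 0) {
    abort("`tau` must be > 0 to derive delta_TS.")
  }
  params$beta_TS / params$tau
}

#' Model mean performance for a given day and phase
#'
#' Phase 1 grows at the combined rate: `(beta_cap + beta_TS) * t + alpha`.
#' Phase 2 keeps only the capacity slope plus the task-specific plateau:
#' `beta_cap * t + beta_TS / tau + alpha`.
#'
#' @param params An [hmm_params] object.
#' @param t Day (session index), `>= 0`; vectorized.
#' @param phase Either `1` or `2`.
#' @return Mean performance level(s), same length as `t`.
#' @export
predict_mean <- function(params, t, phase) {
  if (length(phase) != 1L || !phase %in% c(1, 2)) {
    abort("`phase` must be 1 or 2.")
  }
  if (any(t < 0)) abort("`t` must be >= 0.")
  if (phase == 1) {
    (params$beta_cap + params$beta_TS) * t + params$alpha
  } else {
    params$beta_cap * t + params$beta_TS / params$tau + params$alpha
  }
}

#' Gaussian emission log density
#'
#' Log density of an observed performance level around the phase mean,
#' with noise standard deviation `sigma`.
#'
#' @inheritParams predict_mean
#' @param y Observed level(s); must be finite.
#' @return Log density value(s).
#' @export
emission_logpdf <- function(params, y, t, phase) {
  if (any(!is.finite(y))) abort("`y` must be finite.")
  if (params$sigma <= 0) abort("`sigma` must be > 0.")
  dnorm(y, mean = predict_mean(params, t, phase), sd = params$sigma,
        log = TRUE)
}
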