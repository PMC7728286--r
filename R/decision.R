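# Decision variable of the Bayes-family observers and derived quantities.
#
# With u = x_L - x_R and v = (x_L + x_R)/2 the two category likelihoods
# factorize as
#   p(x | C = 1) = N(u; 0, 2 s^2) N(v; y, sy^2 + s^2/2)
#   p(x | C = 0) = N(x_L; y, s^2 + sy^2) N(x_R; y, s^2 + sy^2)
# (s = sigma_x, sy = sigma_y), so the log posterior ratio is the quadratic
#   d*(u, v) = K - A u^2 + cv (v - y)^2
# with A > 0 and cv > 0; see boundary_coefficients() below.

# K, A, cv for given (possibly assumed) noise/width/prior; vectorized
boundary_coefficients <- function(sigma_x, sigma_y, p_common) {
  if (any(sigma_x <= 0)) stop("`sigma_x` must be positive", call. = FALSE)
  if (any(sigma_y <= 0)) stop("`sigma_y` must be positive", call. = FALSE)
  s2 <- sigma_x^2 + sigma_y^2
  list(
    K = log(p_common / (1 - p_common)) +
      log(s2 / (sigma_x * sqrt(sigma_x^2 + 2 * sigma_y^2))),
    A = 1 / (4 * sigma_x^2) - 1 / (4 * s2),
    cv = 1 / s2 - 1 / (sigma_x^2 + 2 * sigma_y^2)
  )
}

#' Log posterior ratio of the collinear vs non-collinear category
#'
#' \eqn{d^* = \log p(C=1|x_L,x_R) - \log p(C=0|x_L,x_R)} for measurements
#' `x_left`, `x_right` at base eccentricity `eccentricity`, obtained by
#' marginalizing the latent segment positions in closed form. The Bayes
#' observer reports "collinear" when \eqn{d^* \ge 0}.
#'
#' In the degenerate limit `sigma_y -> 0` both categories coincide and
#' \eqn{d^*} equals the log prior ratio for any measurements.
#'
#' @param x_left,x_right measurements (dva); vectorized.
#' @param eccentricity base position \eqn{y} (dva).
#' @param sigma_x measurement noise SD at this eccentricity (> 0).
#' @param sigma_y offset-distribution SD (> 0).
#' @param p_common prior probability of the collinear category.
#' @return numeric vector of log posterior ratios.
#' @export
bayes_log_posterior_ratio <- function(x_left, x_right, eccentricity,
                                      sigma_x, sigma_y, p_common) {
  if (any(sigma_x <= 0) || any(sigma_y <= 0)) {
    stop("noise SDs must be strictly positive", call. = FALSE)
  }
  u <- x_left - x_right
  v <- (x_left + x_right) / 2
  s2 <- sigma_x^2 + sigma_y^2
  log(p_common / (1 - p_common)) +
    dnorm(u, 0, sqrt(2 * sigma_x^2), log = TRUE) +
    dnorm(v, eccentricity, sqrt(sigma_y^2 + sigma_x^2 / 2), log = TRUE) -
    dnorm(x_left, eccentricity, sqrt(s2), log = TRUE) -
    dnorm(x_right, eccentricity, sqrt(s2), log = TRUE)
}

#' Half-width of the Bayesian accept region at fixed mean coordinate
#'
#' At fixed \eqn{v} the accept region of the Bayes observer is
#' \eqn{|u| \le b(v)} with \eqn{b(v)^2 = (K + c_v (v-y)^2)/A}. Returns `NA`
#' where the region is empty (\eqn{d^* < 0} for all `u`). The boundary flares
#' away from the base eccentricity: \eqn{b(v)^2 - b(y)^2 \propto (v-y)^2}.
#'
#' @param v mean measurement coordinate \eqn{(x_L + x_R)/2} (dva); vectorized.
#' @inheritParams bayes_log_posterior_ratio
#' @return half-widths in the difference coordinate (dva), `NA` where empty.
#' @export
bayes_accept_halfwidth <- function(v, eccentricity, sigma_x, sigma_y,
                                   p_common) {
  cf <- boundary_coefficients(sigma_x, sigma_y, p_common)
  b2 <- (cf$K + cf$cv * (v - eccentricity)^2) / cf$A
  ifelse(b2 >= 0, sqrt(pmax(b2, 0)), NA_real_)
}

# assumed quantities entering the decision variable, per model
assumed_noise <- function(params, sigma_true) {
  if (params$model == "noise_mismatch") {
    params$assumed_intercept + params$assumed_slope * sigma_true
  } else {
    sigma_true
  }
}

assumed_width <- function(params) {
  if (params$model %in% c("width_mismatch", "hybrid_dn_width")) {
    params$sigma_y_assumed
  } else {
    params$sigma_y
  }
}

#' History-extended criterion along a session's trial sequence
#'
#' For the `history` model the criterion on trial \eqn{t} is
#' \eqn{\kappa_t = \kappa_0 + \sum_{k=0}^{4} w_k \, \sigma_x(y_{t-k})},
#' where trials before the session start contribute the current trial's
#' noise. Trials must come from a single subject and session and are used in
#' their temporal order (block, then trial index).
#'
#' @param params `observer_params` for the `history` model.
#' @param trials collinearity-task trials from one subject and session.
#' @return criterion (dva, not clipped) per trial, in the input row order.
#' @export
history_criterion <- function(params, trials) {
  stopifnot(inherits(params, "observer_params"))
  if (params$model != "history") {
    stop("`params` must describe the 'history' model", call. = FALSE)
  }
  validate_trials(trials, task = "collinearity")
  if (length(unique(trials$subject_id)) > 1L ||
      length(unique(trials$session)) > 1L) {
    stop("history criterion is defined within a single subject and session",
         call. = FALSE)
  }
  ord <- order(trials$block, trials$trial_index)
  sig <- trial_sigma(params, trials)[ord]
  n <- length(sig)
  w <- params$history_weights
  kap <- rep(params$kappa0, n)
  for (k in 0:4) {
    lagged <- sig  # pre-session lags fall back to the current trial's noise
    if (k > 0 && n > k) lagged[(k + 1):n] <- sig[seq_len(n - k)]
    kap <- kap + w[k + 1] * lagged
  }
  out <- numeric(n)
  out[ord] <- kap
  out
}

# effective (clipped) criterion per trial for the threshold family
effective_criterion <- function(params, trials) {
  sig <- trial_sigma(params, trials)
  kap <- switch(params$model,
    fixed = rep(params$kappa, nrow(trials)),
    lin = params$kappa0 + params$kappa1 * sig,
    nonparametric = params$kappa_levels[
      match_level(trials$eccentricity, params$levels)],
    history = {
      key <- interaction(trials$subject_id, trials$session, drop = TRUE)
      out <- numeric(nrow(trials))
      for (g in levels(key)) {
        idx <- which(key == g)
        out[idx] <- history_criterion(params, trials[idx, , drop = FALSE])
      }
      out
    },
    stop("no criterion for model '", params$model, "'", call. = FALSE))
  pmax(kap, 0)
}
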