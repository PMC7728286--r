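# Exact trial response probabilities for every observer model.

# rule probability (probability the decision rule says "collinear"),
# before the lapse mixture; `idx` restricts to a trial subset
rule_prob_collinear <- function(params, trials, idx = NULL, n_nodes = 25L) {
  if (is.null(idx)) idx <- seq_len(nrow(trials))
  tr <- trials[idx, , drop = FALSE]
  sig <- trial_sigma(params, tr)
  delta <- tr$y_left - tr$y_right
  su <- sqrt(2) * sig
  fam <- model_family(params$model)
  if (fam == "threshold") {
    # criteria may couple trials across the session (history model), so
    # compute them on the full table and subset
    kap <- effective_criterion(params, trials)[idx]
    return(pnorm((kap - delta) / su) - pnorm((-kap - delta) / su))
  }
  sig_a <- assumed_noise(params, sig)
  cf <- boundary_coefficients(sig_a, assumed_width(params), params$p_common)
  m <- (tr$y_left + tr$y_right) / 2
  tau <- sig / sqrt(2)
  gl <- gauss_legendre(n_nodes)
  p <- if (fam == "boundary") {
    .cpp_p_boundary(m, delta, tr$eccentricity, rep_len(cf$K, nrow(tr)),
                    rep_len(cf$A, nrow(tr)), rep_len(cf$cv, nrow(tr)),
                    tau, su, gl$x, gl$w)
  } else if (fam == "decision_noise") {
    glu <- gauss_legendre(15L)
    .cpp_p_decision_noise(m, delta, tr$eccentricity,
                          rep_len(cf$K, nrow(tr)), rep_len(cf$A, nrow(tr)),
                          rep_len(cf$cv, nrow(tr)), tau, su,
                          rep_len(params$sigma_d, nrow(tr)),
                          gl$x, gl$w, glu$x, glu$w)
  } else {
    stop("model '", params$model, "' has no collinearity response rule",
         call. = FALSE)
  }
  if (any(p < -1e-6) || any(p > 1 + 1e-6)) {
    stop("quadrature failure: response probability outside [0, 1]",
         call. = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

#' Probability of reporting "collinear"
#'
#' Exact response probability
#' \eqn{\lambda/2 + (1-\lambda)\,P(\mathrm{rule\ says\ collinear} \mid y_L, y_R, \sigma_x)}
#' for each trial. For the threshold family (`fixed`, `lin`, `history`,
#' `nonparametric`) the rule probability is a difference of normal CDFs in
#' the measured offset; for the Bayes family it is obtained by piecewise
#' Gauss-Legendre quadrature of the accept region against the measurement
#' distribution (panels split at the boundary's cusp and roots, `n_nodes`
#' nodes per panel); the decision-noise models additionally integrate
#' \eqn{\Phi(d^*/\sigma_d)} over the difference coordinate.
#'
#' Mismatch variants substitute assumed noise/width inside the decision
#' variable only; the measurement distribution always uses the true
#' \eqn{\sigma_x}.
#'
#' @param params an [observer_params()] (any model except `height`).
#' @param trials collinearity-task trials.
#' @param n_nodes quadrature nodes per panel (Bayes family).
#' @return response probabilities, one per trial.
#' @examples
#' p <- observer_params("fixed", sigma_x = 0.5, levels = 0, kappa = sqrt(2) * 0.5)
#' tr <- generate_collinearity_trials(collinearity_design(eccentricity_levels = 0),
#'                                    10, seed = 1)
#' p_collinear_response(p, tr)
#' @export
p_collinear_response <- function(params, trials, n_nodes = 25L) {
  stopifnot(inherits(params, "observer_params"))
  validate_trials(trials, task = "collinearity")
  if (params$model == "height") {
    stop("the height model has no collinearity response rule", call. = FALSE)
  }
  p <- rule_prob_collinear(params, trials, n_nodes = n_nodes)
  params$lapse / 2 + (1 - params$lapse) * p
}

#' Probability of reporting "right segment higher"
#'
#' The optimal height judgment rule responds "right higher" whenever
#' `x_R > x_L`, giving
#' \eqn{\lambda/2 + (1-\lambda)\,\Phi((y_R - y_L)/(\sqrt{2}\sigma_x))}.
#'
#' @param params an [observer_params()]; only its noise profile and lapse
#'   are used.
#' @param trials height-task trials.
#' @return response probabilities, one per trial.
#' @export
p_right_higher <- function(params, trials) {
  stopifnot(inherits(params, "observer_params"))
  validate_trials(trials, task = "height")
  sig <- trial_sigma(params, trials)
  p <- pnorm((trials$y_right - trials$y_left) / (sqrt(2) * sig))
  params$lapse / 2 + (1 - params$lapse) * p
}

#' Log-likelihood of a responded trial table
#'
#' Sums the log probability of the recorded response over trials, using
#' [p_collinear_response()] or [p_right_higher()] (and its complement) as
#' appropriate for each trial's task. Zero-probability responses (possible
#' with `lapse = 0`) yield `-Inf` with a warning.
#'
#' @inheritParams p_collinear_response
#' @return a list with elements `total` (scalar log-likelihood) and
#'   `pointwise` (per-trial log-likelihood vector, used by [psis_loo()]).
#' @export
dataset_log_likelihood <- function(params, trials, n_nodes = 25L) {
  stopifnot(inherits(params, "observer_params"))
  validate_trials(trials, need_response = TRUE)
  pw <- numeric(nrow(trials))
  is_h <- trials$task == "height"
  if (any(is_h)) {
    p <- p_right_higher(params, trials[is_h, , drop = FALSE])
    resp <- trials$response[is_h]
    pw[is_h] <- log(ifelse(resp == "right_higher", p, 1 - p))
  }
  if (any(!is_h)) {
    p <- p_collinear_response(params, trials[!is_h, , drop = FALSE],
                              n_nodes = n_nodes)
    resp <- trials$response[!is_h]
    pw[!is_h] <- log(ifelse(resp == "collinear", p, 1 - p))
  }
  if (any(pw == -Inf)) {
    warning("zero-probability response(s): log-likelihood is -Inf")
  }
  list(total = sum(pw), pointwise = pw)
}

#' Simulate observer responses
#'
#' Forward-simulates the generative model: per trial, measurements
#' \eqn{x_L \sim N(y_L, \sigma_x^2)}, \eqn{x_R \sim N(y_R, \sigma_x^2)} are
#' drawn, the model's decision rule is applied, and with probability
#' \eqn{\lambda} the response is replaced by a uniformly random label.
#' Ties \eqn{d^* = 0} (or `|u|` exactly at the criterion) report "collinear".
#'
#' @param params an [observer_params()]; the `height` model simulates
#'   height-task trials, every other model collinearity-task trials.
#' @param trials trials of the matching task.
#' @param seed integer RNG seed.
#' @return `trials` with the `response` column filled.
#' @export
simulate_responses <- function(params, trials, seed) {
  stopifnot(inherits(params, "observer_params"))
  task <- if (params$model == "height") "height" else "collinearity"
  validate_trials(trials, task = task)
  n <- nrow(trials)
  sig <- trial_sigma(params, trials)
  with_seed(seed, {
    x_left <- rnorm(n, trials$y_left, sig)
    x_right <- rnorm(n, trials$y_right, sig)
    fam <- model_family(params$model)
    response <- if (fam == "height") {
      ifelse(x_right > x_left, "right_higher", "left_higher")
    } else {
      u <- x_left - x_right
      says_collinear <- if (fam == "threshold") {
        abs(u) <= effective_criterion(params, trials)
      } else {
        d <- bayes_log_posterior_ratio(x_left, x_right, trials$eccentricity,
                                       assumed_noise(params, sig),
                                       assumed_width(params), params$p_common)
        if (fam == "decision_noise") d <- d + rnorm(n, 0, params$sigma_d)
        d >= 0
      }
      ifelse(says_collinear, "collinear", "noncollinear")
    }
    lab <- response_labels(task)
    lapsed <- runif(n) < params$lapse
    response[lapsed] <- sample(lab, sum(lapsed), replace = TRUE)
    trials$response <- response
    trials
  })
}
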