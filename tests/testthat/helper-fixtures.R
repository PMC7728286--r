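# shared fixtures: built in code, no stored data

fx_levels <- c(0, 4.8, 9.6, 16.8)
fx_noise <- c(0.35, 0.55, 1, 2)  # realistic noise profile, dva

one_level_design <- function(level = 4.8, offset_sd = 0.48, prior = 0.5) {
  collinearity_design(eccentricity_levels = level, offset_sd = offset_sd,
                      prior_collinear = prior)
}

# a trial table with fully specified stimuli (bypasses the generator)
stim_trials <- function(y_left, y_right, eccentricity, task = "collinearity",
                        response = NA_character_) {
  n <- max(length(y_left), length(y_right), length(eccentricity))
  df <- data.frame(
    subject_id = "fx", session = 1L, block = 1L, trial_index = seq_len(n),
    task = task, eccentricity = rep_len(eccentricity, n),
    y_left = rep_len(y_left, n), y_right = rep_len(y_right, n),
    category = if (task == "collinearity") "noncollinear" else "left_higher",
    response = rep_len(response, n), stringsAsFactors = FALSE)
  class(df) <- c("cj_trials", "data.frame")
  df
}

# canonical "realistic" heuristic observer: criterion grows strongly with
# noise (boundaries 0.6-2.75 dva across levels), overall efficiency ~0.95
fx_lin_params <- function(lapse = 0.03) {
  observer_params("lin", sigma_x = fx_noise, levels = fx_levels,
                  lapse = lapse, kappa0 = 0.15, kappa1 = 1.3)
}
fx_fixed_params <- function(lapse = 0.03, kappa = 1) {
  observer_params("fixed", sigma_x = fx_noise, levels = fx_levels,
                  lapse = lapse, kappa = kappa)
}
fx_bayes_params <- function(lapse = 0.03, p_common = 0.5) {
  observer_params("bayes", sigma_x = fx_noise, levels = fx_levels,
                  lapse = lapse, p_common = p_common)
}

# brute-force log posterior ratio by 1-D numeric integration of the latent
# positions (independent oracle for bayes_log_posterior_ratio)
brute_log_posterior_ratio <- function(xL, xR, y, sx, sy, p) {
  f1 <- function(t) dnorm(xL, t, sx) * dnorm(xR, t, sx) * dnorm(t, y, sy)
  L1 <- integrate(f1, y - 12 * sy, y + 12 * sy, rel.tol = 1e-12)$value
  L0 <- integrate(function(t) dnorm(xL, t, sx) * dnorm(t, y, sy),
                  y - 12 * sy, y + 12 * sy, rel.tol = 1e-12)$value *
    integrate(function(t) dnorm(xR, t, sx) * dnorm(t, y, sy),
              y - 12 * sy, y + 12 * sy, rel.tol = 1e-12)$value
  log(p / (1 - p)) + log(L1) - log(L0)
}

# slow independent quadrature of the Bayes response probability: trapezoid
# over the mean coordinate using the closed-form accept half-width
trapezoid_p_bayes <- function(yL, yR, y, sx, sy, p, n_grid = 2e5) {
  m <- (yL + yR) / 2
  tau <- sx / sqrt(2)
  v <- seq(m - 9 * tau, m + 9 * tau, length.out = n_grid)
  b <- bayes_accept_halfwidth(v, y, sx, sy, p)
  b[is.na(b)] <- 0
  g <- pnorm((b - (yL - yR)) / (sqrt(2) * sx)) -
    pnorm((-b - (yL - yR)) / (sqrt(2) * sx))
  sum(dnorm(v, m, tau) * g) * (v[2] - v[1])
}
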