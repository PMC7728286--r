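test_that("log posterior ratio matches brute-force latent-variable integration", {
  # frozen value computed with the integrate()-based oracle in the helper
  expect_equal(bayes_log_posterior_ratio(0.3, -0.3, 0, 0.5, 0.48, 0.5),
               -0.0419630368, tolerance = 1e-8)
  cases <- list(c(5.1, 4.2, 4.8, 1.0, 0.48, 0.3),
                c(-1, 2, 0, 2, 0.48, 0.7),
                c(17.2, 16.5, 16.8, 0.35, 1.2, 0.55))
  for (cs in cases) {
    expect_equal(bayes_log_posterior_ratio(cs[1], cs[2], cs[3], cs[4], cs[5],
                                           cs[6]),
                 do.call(brute_log_posterior_ratio, as.list(cs)),
                 tolerance = 1e-9)
  }
})

test_that("log posterior ratio: symmetry and degenerate width limit", {
  expect_equal(bayes_log_posterior_ratio(0.7, -0.2, 0, 0.5, 0.48, 0.4),
               bayes_log_posterior_ratio(-0.2, 0.7, 0, 0.5, 0.48, 0.4))
  # sigma_y -> 0: categories coincide, d* -> log prior ratio
  expect_equal(bayes_log_posterior_ratio(1.3, -0.4, 0, 0.5, 1e-7, 0.3),
               log(0.3 / 0.7), tolerance = 1e-6)
  expect_error(bayes_log_posterior_ratio(0, 0, 0, -1, 0.48, 0.5), "positive")
})

test_that("accept half-width matches bisection on d* and flares quadratically", {
  sx <- 0.6; sy <- 0.48; p <- 0.55; y <- 4.8
  for (v in c(4.8, 5.1, 5.9)) {
    b <- bayes_accept_halfwidth(v, y, sx, sy, p)
    root <- uniroot(function(u) {
      bayes_log_posterior_ratio(v + u / 2, v - u / 2, y, sx, sy, p)
    }, c(1e-9, 20), tol = 1e-12)$root
    expect_equal(b, root, tolerance = 1e-8)
  }
  # b(v)^2 - b(y)^2 proportional to (v - y)^2, nonnegative slope
  vv <- y + c(0.3, 0.7, 1.4)
  gain <- bayes_accept_halfwidth(vv, y, sx, sy, p)^2 -
    bayes_accept_halfwidth(y, y, sx, sy, p)^2
  slope <- gain / (vv - y)^2
  expect_true(all(slope > 0))
  expect_equal(max(slope) - min(slope), 0, tolerance = 1e-10)
  # boundary depends on v, not only on the measured difference
  expect_gt(bayes_accept_halfwidth(y + 1, y, sx, sy, p),
            bayes_accept_halfwidth(y, y, sx, sy, p))
})

test_that("accept region is empty when the prior forbids collinear at v = y", {
  # p_common small enough drives K < 0: no u yields d* >= 0 near v = y
  b <- bayes_accept_halfwidth(4.8, 4.8, 1, 0.48, 0.1)
  expect_true(is.na(b))
  expect_lt(bayes_log_posterior_ratio(4.8, 4.8, 4.8, 1, 0.48, 0.1), 0)
})

test_that("threshold-family response probabilities are exact normal CDFs", {
  # frozen: kappa = sqrt(2) sigma, zero offset -> 2 Phi(1) - 1
  sx <- 0.5
  par <- observer_params("fixed", sigma_x = sx, levels = 4.8,
                         kappa = sqrt(2) * sx, lapse = 0)
  tt <- stim_trials(4.8, 4.8, 4.8)
  expect_equal(p_collinear_response(par, tt), 0.6826894921, tolerance = 1e-9)
  # Lin with zero slope equals Fixed to machine precision
  parl <- observer_params("lin", sigma_x = sx, levels = 4.8,
                          kappa0 = sqrt(2) * sx, kappa1 = 0, lapse = 0)
  tt2 <- stim_trials(c(4.8, 5.2, 4.1), c(4.8, 4.7, 4.9), 4.8)
  expect_identical(p_collinear_response(par, tt2),
                   p_collinear_response(parl, tt2))
  # monotone decreasing in |offset|
  offs <- seq(0, 3, by = 0.5)
  tt3 <- stim_trials(4.8 + offs, 4.8, 4.8)
  expect_true(all(diff(p_collinear_response(par, tt3)) < 0))
})

test_that("pure lapse forces 0.5 for every model", {
  tt <- stim_trials(5.3, 4.4, 4.8)
  mk <- list(
    observer_params("fixed", 0.5, 4.8, lapse = 1, kappa = 1),
    observer_params("lin", 0.5, 4.8, lapse = 1, kappa0 = 1, kappa1 = 0.3),
    observer_params("bayes", 0.5, 4.8, lapse = 1, p_common = 0.4),
    observer_params("bayes_dn", 0.5, 4.8, lapse = 1, p_common = 0.5,
                    sigma_d = 1),
    observer_params("nonparametric", 0.5, 4.8, lapse = 1, kappa_levels = 0.8))
  for (par in mk) {
    expect_equal(p_collinear_response(par, tt), 0.5, tolerance = 1e-12)
  }
  ph <- observer_params("height", 0.5, 4.8, lapse = 1)
  th <- stim_trials(4.3, 5.6, 4.8, task = "height")
  expect_equal(p_right_higher(ph, th), 0.5, tolerance = 1e-12)
})

test_that("response probabilities live in [lapse/2, 1 - lapse/2]", {
  lam <- 0.1
  tt <- stim_trials(c(4.8, 5.0, 6.5, 3.0), c(4.8, 4.9, 4.4, 5.2), 4.8)
  pars <- list(
    observer_params("fixed", 0.7, 4.8, lapse = lam, kappa = 1),
    observer_params("bayes", 0.7, 4.8, lapse = lam, p_common = 0.3),
    observer_params("noise_mismatch", 0.7, 4.8, lapse = lam,
                    assumed_intercept = 0.1, assumed_slope = 1.2),
    observer_params("width_mismatch", 0.7, 4.8, lapse = lam, p_common = 0.6,
                    sigma_y_assumed = 1),
    observer_params("hybrid_dn_width", 0.7, 4.8, lapse = lam, p_common = 0.5,
                    sigma_y_assumed = 0.3, sigma_d = 0.7))
  for (par in pars) {
    p <- p_collinear_response(par, tt)
    expect_true(all(p >= lam / 2 - 1e-12 & p <= 1 - lam / 2 + 1e-12))
  }
})

test_that("Bayes response probability agrees with independent quadrature and MC", {
  for (cs in list(c(5.1, 4.8, 4.8, 0.5, 0.5),
                  c(5.1, 4.8, 4.8, 2.0, 0.5),
                  c(5.0, 4.9, 4.8, 1.0, 0.3),
                  c(4.6, 4.8, 4.8, 0.2, 0.7))) {
    par <- observer_params("bayes", sigma_x = cs[4], levels = cs[3],
                           lapse = 0, p_common = cs[5])
    tt <- stim_trials(cs[1], cs[2], cs[3])
    p <- p_collinear_response(par, tt)
    expect_lt(abs(p - trapezoid_p_bayes(cs[1], cs[2], cs[3], cs[4], 0.48,
                                        cs[5])), 2e-5)
    n <- 2e5
    big <- tt[rep(1, n), ]; big$trial_index <- seq_len(n)
    p_mc <- mean(simulate_responses(par, big, seed = 77)$response ==
                   "collinear")
    expect_lt(abs(p - p_mc), 3 * sqrt(max(p_mc * (1 - p_mc), 1e-7) / n))
  }
})

test_that("mismatch variants reduce to Bayes at matched parameters", {
  tt <- stim_trials(c(5.2, 4.75, 4.4), c(4.8, 4.85, 5.0), 4.8)
  pb <- observer_params("bayes", 0.7, 4.8, lapse = 0.02, p_common = 0.5)
  pn <- observer_params("noise_mismatch", 0.7, 4.8, lapse = 0.02,
                        assumed_intercept = 0, assumed_slope = 1)
  expect_equal(p_collinear_response(pn, tt), p_collinear_response(pb, tt),
               tolerance = 1e-12)
  pw <- observer_params("width_mismatch", 0.7, 4.8, lapse = 0.02,
                        p_common = 0.5, sigma_y_assumed = 0.48)
  expect_equal(p_collinear_response(pw, tt), p_collinear_response(pb, tt),
               tolerance = 1e-12)
  # decision noise vanishing: converges to the deterministic Bayes rule
  pd <- observer_params("bayes_dn", 0.7, 4.8, lapse = 0.02, p_common = 0.5,
                        sigma_d = 1e-6)
  expect_equal(p_collinear_response(pd, tt), p_collinear_response(pb, tt),
               tolerance = 1e-4)
  ph <- observer_params("hybrid_dn_width", 0.7, 4.8, lapse = 0.02,
                        p_common = 0.5, sigma_y_assumed = 0.48,
                        sigma_d = 1e-6)
  expect_equal(p_collinear_response(ph, tt), p_collinear_response(pb, tt),
               tolerance = 1e-4)
})

test_that("height judgment probability is the signed-offset CDF", {
  sx <- 0.5
  ph <- observer_params("height", sigma_x = sx, levels = 4.8, lapse = 0)
  expect_equal(p_right_higher(ph, stim_trials(4.8, 4.8, 4.8, task = "height")),
               0.5)
  # frozen: offset sqrt(2) sigma -> Phi(1)
  expect_equal(p_right_higher(ph, stim_trials(4.8, 4.8 + sqrt(2) * sx, 4.8,
                                              task = "height")),
               0.8413447461, tolerance = 1e-9)
})

test_that("dataset log-likelihood: base case, additivity, naive oracle", {
  par <- fx_fixed_params(lapse = 0.04)
  d <- make_default_design()
  tr <- generate_collinearity_trials(d, 10, seed = 14)
  tr <- simulate_responses(par, tr, seed = 15)
  ll <- dataset_log_likelihood(par, tr)
  # independently coded per-trial product for the fixed rule
  sig <- fx_noise[match(tr$eccentricity, fx_levels)]
  delta <- tr$y_left - tr$y_right
  p_rule <- pnorm((1 - delta) / (sqrt(2) * sig)) -
    pnorm((-1 - delta) / (sqrt(2) * sig))
  p_coll <- 0.02 + 0.96 * p_rule
  p_resp <- ifelse(tr$response == "collinear", p_coll, 1 - p_coll)
  expect_equal(ll$total, log(prod(p_resp)), tolerance = 1e-10)
  expect_equal(ll$pointwise, log(p_resp), tolerance = 1e-10)
  # concatenation additivity
  a <- dataset_log_likelihood(par, tr[1:4, ])
  b <- dataset_log_likelihood(par, tr[5:10, ])
  expect_equal(ll$total, a$total + b$total)
  # single trial at p = 0.5 gives log 0.5
  pl <- observer_params("fixed", 0.5, 4.8, kappa = 1, lapse = 1)
  one <- tr[1, ]; one$eccentricity <- 4.8
  one$response <- "collinear"
  pl1 <- observer_params("fixed", 0.5, 4.8, kappa = 1, lapse = 1)
  expect_equal(dataset_log_likelihood(pl1, one)$total, log(0.5))
})

test_that("zero-probability responses flag -Inf", {
  par <- observer_params("fixed", 0.5, 4.8, kappa = 0, lapse = 0)
  one <- stim_trials(5.6, 4.0, 4.8, response = "collinear")
  one$category <- "noncollinear"
  expect_warning(ll <- dataset_log_likelihood(par, one), "zero-probability")
  expect_identical(ll$total, -Inf)
})

test_that("history criterion: hand-computed toy sequence and reductions", {
  w <- c(0.1, 0.2, -0.1, 0.05, 0.3)
  par <- observer_params("history", sigma_x = fx_noise, levels = fx_levels,
                         kappa0 = 0.2, history_weights = w)
  ecc_seq <- c(0, 4.8, 9.6, 0, 16.8, 4.8)
  tt <- stim_trials(ecc_seq, ecc_seq, ecc_seq)
  kap <- history_criterion(par, tt)
  sig_seq <- fx_noise[match(ecc_seq, fx_levels)]
  expected <- vapply(seq_along(sig_seq), function(t) {
    s <- vapply(0:4, function(k) {
      if (t - k >= 1) sig_seq[t - k] else sig_seq[t]
    }, numeric(1))
    0.2 + sum(w * s)
  }, numeric(1))
  expect_equal(kap, expected, tolerance = 1e-12)
  # all weights on lag 0: reduces to Lin
  par0 <- observer_params("history", sigma_x = fx_noise, levels = fx_levels,
                          kappa0 = 0.2, history_weights = c(0.7, 0, 0, 0, 0))
  parl <- observer_params("lin", sigma_x = fx_noise, levels = fx_levels,
                          kappa0 = 0.2, kappa1 = 0.7)
  expect_equal(p_collinear_response(par0, tt), p_collinear_response(parl, tt))
  # constant eccentricity: kappa_t constant at kappa0 + sigma * sum(w)
  cc <- stim_trials(rep(9.6, 7), rep(9.6, 7), 9.6)
  expect_equal(history_criterion(par, cc), rep(0.2 + 1 * sum(w), 7))
  # mixed sessions rejected
  tt2 <- tt; tt2$session <- c(1L, 1L, 1L, 2L, 2L, 2L)
  expect_error(history_criterion(par, tt2), "single subject and session")
})

test_that("observer_params validates model-specific fields and counts", {
  expect_error(observer_params("fixed", 0.5, 4.8), "requires")
  expect_error(observer_params("fixed", 0.5, 4.8, kappa = 1, p_common = 0.5),
               "not used")
  expect_error(observer_params("bayes", -0.5, 4.8, p_common = 0.5),
               "positive")
  expect_error(observer_params("history", 0.5, 4.8, kappa0 = 0,
                               history_weights = 1:3), "length 5")
  expect_error(observer_params("noise_mismatch", 0.5, 4.8,
                               assumed_intercept = 0, assumed_slope = 0),
               "positive")
  # free-parameter counts per model (unconstrained / constrained)
  d <- make_default_design()
  counts <- c(fixed = 6, bayes = 6, lin = 7, noise_mismatch = 7,
              width_mismatch = 7, bayes_dn = 7, hybrid_dn_width = 8,
              nonparametric = 9, history = 11, height = 5)
  for (m in names(counts)) {
    expect_identical(nrow(prior_spec(m, d)), as.integer(counts[[m]]),
                     info = m)
  }
  con <- setNames(fx_noise, c("0", "4.8", "9.6", "16.8"))
  expect_identical(nrow(prior_spec("fixed", d, constrained_noise = con)), 2L)
  expect_identical(nrow(prior_spec("bayes", d, constrained_noise = con)), 2L)
  expect_identical(nrow(prior_spec("lin", d, constrained_noise = con)), 3L)
})
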