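test_that("offset binning matches the printed interval convention", {
  # offset exactly -3.31 falls in the leftmost bin (-Inf, -3.31]
  tt <- stim_trials(c(4.8 - 3.31, 4.8 - 3.30, 4.8 + 3.31, 4.8 + 3.32),
                    4.8, 4.8, response = "collinear")
  tab <- bin_psychometric(tt)
  counts <- tapply(tab$n, tab$bin, sum)
  expect_identical(unname(counts[["(-Inf,-3.31]"]]), 1L)
  expect_identical(unname(counts[["(-3.31,-2.08]"]]), 1L)
  expect_identical(unname(counts[["(2.08,3.31]"]]), 1L)
  expect_identical(unname(counts[["(3.31, Inf]"]]), 1L)
})

test_that("binning is exhaustive, exclusive, and flags empty bins as NA", {
  set.seed(61)
  off <- rnorm(500, 0, 1.5)
  tt <- stim_trials(4.8 + off, 4.8, 4.8,
                    response = sample(c("collinear", "noncollinear"), 500,
                                      TRUE))
  tab <- bin_psychometric(tt)
  expect_identical(sum(tab$n), 500L)           # every trial in exactly one bin
  expect_identical(nrow(tab), 9L)              # 9 bins x 1 eccentricity
  expect_true(all(is.na(tab$prop[tab$n == 0])))
  expect_true(all(tab$prop[tab$n > 0] >= 0 & tab$prop[tab$n > 0] <= 1))
  # all-collinear responses give proportion 1 everywhere observed
  tt$response <- "collinear"
  tab1 <- bin_psychometric(tt)
  expect_true(all(tab1$prop[tab1$n > 0] == 1))
})

test_that("binned simulated curves match analytic response probabilities", {
  par <- fx_fixed_params(lapse = 0.02)
  d <- make_default_design()
  tr <- generate_collinearity_trials(d, 4e4, seed = 62)
  tr <- simulate_responses(par, tr, seed = 63)
  tab <- bin_psychometric(tr)
  p_an <- p_collinear_response(par, tr)
  bin <- cut(tr$y_left - tr$y_right, collinobs:::offset_breaks(), right = TRUE)
  cell <- interaction(factor(tr$eccentricity, levels = sort(unique(tr$eccentricity))),
                      bin, drop = FALSE)
  expected <- as.vector(tapply(p_an, cell, mean, default = NA_real_))
  keep <- tab$n >= 30
  z <- (tab$prop[keep] - expected[keep]) /
    sqrt(expected[keep] * (1 - expected[keep]) / tab$n[keep])
  expect_true(all(abs(z) < 3.5))
  expect_gt(mean(abs(z) < 3), 0.97)
})

test_that("optimal accuracy: ordering in noise, chance limit, analytic check", {
  d <- make_default_design()
  noise <- setNames(c(0.3, 0.6, 1.2, 8), c("0", "4.8", "9.6", "16.8"))
  acc <- optimal_accuracy(noise, d, n_sim = 2e4, seed = 64)
  expect_true(all(diff(acc$accuracy) < 3 * sqrt(2) * max(acc$se)))
  expect_true(all(acc$accuracy >= 0.5 - 3 * acc$se))
  # huge noise: accuracy collapses to the chance probability 0.5
  expect_lt(abs(acc$accuracy[4] - 0.5), 4 * acc$se[4])
  # analytic (Rao-Blackwellized) check at one level: average the exact
  # response probability over the category-conditional stimulus densities
  par <- observer_params("bayes", sigma_x = 0.6, levels = 4.8, lapse = 0,
                         p_common = 0.5)
  d1 <- one_level_design()
  tr <- generate_collinearity_trials(d1, 2e4, seed = 65)
  p <- p_collinear_response(par, tr)
  p_correct <- ifelse(tr$category == "collinear", p, 1 - p)
  expect_lt(abs(mean(p_correct) - acc$accuracy[2]),
            3 * sqrt(acc$se[2]^2 + var(p_correct) / length(p_correct)))
})

test_that("efficiency: identity case and random-responder case", {
  d <- one_level_design()
  noise <- c("4.8" = 0.6)
  acc <- optimal_accuracy(noise, d, n_sim = 5e4, seed = 66)
  par <- observer_params("bayes", sigma_x = 0.6, levels = 4.8, lapse = 0,
                         p_common = 0.5)
  tr <- generate_collinearity_trials(d, 2e4, seed = 67)
  tr <- simulate_responses(par, tr, seed = 68)
  eff <- efficiency(tr, acc)
  expect_equal(eff$efficiency, 1, tolerance = 0.02)  # self-efficiency ~ 1
  # a pure random responder achieves ~ 0.5 / optimal
  trr <- tr
  set.seed(680)
  trr$response <- sample(c("collinear", "noncollinear"), nrow(tr), TRUE)
  effr <- efficiency(trr, acc)
  expect_equal(effr$efficiency, 0.5 / eff$optimal_overall, tolerance = 0.03)
  expect_lt(effr$efficiency, 1)
})

test_that("Lin-observer efficiency against the Bayes-optimal benchmark is reported", {
  d <- make_default_design()
  gen <- fx_lin_params()
  tr <- simulate_responses(gen, generate_collinearity_trials(d, 2400,
                                                             seed = 90),
                           seed = 91)
  noise <- setNames(fx_noise, c("0", "4.8", "9.6", "16.8"))
  acc <- optimal_accuracy(noise, d, n_sim = 2e4, seed = 92)
  eff <- efficiency(tr, acc)
  # a heuristic observer with typical fitted parameters sits just below
  # optimal; reported rather than hard-asserted (MC noise at this scale)
  message(sprintf("Lin-vs-optimal efficiency: %.3f", eff$efficiency))
  expect_gt(eff$efficiency, 0.5)
  expect_lt(eff$efficiency, 1.05)
  expect_true(all(eff$table$observed >= 0 & eff$table$observed <= 1))
})

test_that("posterior predictive curves: point mass and single-draw contracts", {
  d <- one_level_design()
  par <- observer_params("fixed", 0.6, 4.8, kappa = 0.8, lapse = 0.02)
  tr <- simulate_responses(
    par, generate_collinearity_trials(d, 400, seed = 69), seed = 70)
  post <- sample_posterior("fixed", tr, prior_spec("fixed", d), n_chains = 2,
                           n_samples = 60, burn_in = 20, seed = 71)
  # point-mass posterior: zero-width bands
  pm <- post
  pm$draws <- post$draws[rep(1, 120), ]
  curves <- posterior_predictive_curves(pm, tr, n_draws = 30)
  expect_true(all(curves$sd[curves$n > 0] == 0))
  # single draw equals that draw's analytic curve
  one <- posterior_predictive_curves(post, tr, n_draws = 1)
  par1 <- collinobs:::vector_to_params(post$prior, post$draws[1, ])
  p1 <- p_collinear_response(par1, tr)
  bin <- cut(tr$y_left - tr$y_right, collinobs:::offset_breaks(),
             right = TRUE)
  expected <- as.vector(tapply(p1, bin, mean, default = NA_real_))
  expect_equal(one$mean, expected, tolerance = 1e-10)
  expect_true(all(one$sd == 0))
  # matched generator/fitted model: observed curve inside mean +/- 2 SD-ish
  obs <- bin_psychometric(tr)
  full <- posterior_predictive_curves(post, tr, n_draws = 40)
  keep <- obs$n >= 20
  band <- 2 * sqrt(full$sd[keep]^2 + obs$se[keep]^2 + 1e-6)
  expect_gt(mean(abs(obs$prop[keep] - full$mean[keep]) <= band), 0.9)
})

test_that("height-noise import recovers a known profile (scaled)", {
  d <- make_default_design()
  par <- observer_params("height", sigma_x = fx_noise, levels = fx_levels,
                         lapse = 0.02)
  tr <- simulate_responses(par, generate_height_trials(d, 960, seed = 72),
                           seed = 73)
  imp <- import_height_noise(tr, d, n_chains = 2, n_samples = 100,
                             burn_in = 40, seed = 74)
  expect_gt(cor(imp$posterior_mean, fx_noise), 0.9)
  expect_gt(cor(imp$map, fx_noise), 0.9)
  # the largest noise SD is only weakly identified from Vernier offsets of
  # SD ~0.68 dva, so its posterior carries a long upper tail; the smaller
  # levels recover tightly
  expect_equal(unname(imp$posterior_mean[1:3]), fx_noise[1:3],
               tolerance = 0.35)
  expect_lt(abs(imp$posterior_mean[[4]] - fx_noise[4]), 2.5)
  # degenerate single-level data error for missing levels
  one_lv <- tr[tr$eccentricity == 4.8, ]
  expect_error(import_height_noise(one_lv, d), "lack eccentricity")
})

test_that("recovery harnesses run end to end at toy scale", {
  d <- one_level_design()
  par <- observer_params("fixed", 0.6, 4.8, kappa = 0.8, lapse = 0.02)
  rec <- parameter_recovery(par, d, n_trials = 600, n_replicates = 2,
                            method = "map", seed = 75, maxit = 300)
  expect_identical(nrow(rec), 2L * 3L)  # 3 free params x 2 replicates
  kap <- rec[rec$parameter == "kappa", ]
  expect_true(all(abs(kap$error) < 0.25))
  # single-model recovery: trivial 1x1 confusion
  mr <- model_recovery(list(fixed = par), d, n_subjects = 2, n_trials = 300,
                       seed = 76, n_chains = 2, n_samples = 60, burn_in = 20,
                       maxit = 150)
  expect_identical(dim(mr$confusion), c(1L, 1L))
  expect_identical(unname(mr$confusion[1, 1]), 2L)
})
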