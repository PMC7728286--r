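# Downstream analyses: psychometric binning, height-task noise import,
# suboptimality/efficiency, posterior predictive curves, recovery harnesses.

default_offset_edges <- function() c(0.38, 1.17, 2.08, 3.31)

offset_breaks <- function(edges = default_offset_edges()) {
  if (any(edges <= 0) || is.unsorted(edges, strictly = TRUE)) {
    stop("`edges` must be strictly increasing positive offsets", call. = FALSE)
  }
  c(-Inf, -rev(edges), edges, Inf)
}

#' Bin trials into psychometric offset bins
#'
#' Assigns each trial's vertical offset `y_left - y_right` to half-open bins
#' (left-open, right-closed), by default
#' \eqn{(-\infty,-3.31], (-3.31,-2.08], \ldots, (3.31,\infty)} dva, and
#' tabulates the proportion of "collinear" (collinearity task) or
#' "right higher" (height task) responses per eccentricity level and bin.
#' Empty bins yield `NA` proportions, not zero.
#'
#' @param trials responded trial table (one task).
#' @param edges positive offsets defining symmetric bin boundaries.
#' @return a `cj_psychometric` data frame with per (eccentricity, bin) rows:
#'   trial count `n`, response count `k`, proportion `prop`, binomial
#'   `se`.
#' @export
bin_psychometric <- function(trials, edges = default_offset_edges()) {
  validate_trials(trials, need_response = TRUE)
  task <- unique(trials$task)
  if (length(task) != 1L) stop("mixed-task trial table", call. = FALSE)
  breaks <- offset_breaks(edges)
  offset <- trials$y_left - trials$y_right
  bin <- cut(offset, breaks = breaks, right = TRUE)
  hit <- trials$response ==
    (if (task == "collinearity") "collinear" else "right_higher")
  ecc <- sort(unique(trials$eccentricity))
  eccf <- factor(trials$eccentricity, levels = ecc)
  grid <- expand.grid(eccentricity = ecc, bin = levels(bin),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # ecc varies fastest in both expand.grid and column-stacked tables
  grid$n <- as.vector(table(eccf, bin))
  grid$k <- as.vector(tapply(hit, list(eccf, bin), sum, default = 0L))
  grid$prop <- ifelse(grid$n > 0, grid$k / grid$n, NA_real_)
  grid$se <- ifelse(grid$n > 0,
                    sqrt(pmax(grid$prop * (1 - grid$prop), 0) / grid$n),
                    NA_real_)
  attr(grid, "task") <- task
  attr(grid, "edges") <- edges
  class(grid) <- c("cj_psychometric", "data.frame")
  grid
}

#' Import noise parameters from the height judgment task
#'
#' Fits the `height` model (four noise SDs plus lapse) to height-task data by
#' [sample_posterior()] and returns the per-level posterior-mean and MAP
#' noise values, for use as `constrained_noise` in [prior_spec()] when
#' fitting the collinearity task with an independently estimated noise
#' profile.
#'
#' @param trials responded height-task trials covering every design level.
#' @param design the task design (levels and offset width).
#' @param ... passed to [sample_posterior()] (chains, draws, seed, ...).
#' @return a list with named vectors `posterior_mean` and `map` (noise SD
#'   per level) and the full `posterior`.
#' @export
import_height_noise <- function(trials, design = make_default_design(), ...) {
  validate_trials(trials, task = "height", need_response = TRUE)
  missing_lv <- setdiff(design$eccentricity_levels,
                        unique(trials$eccentricity))
  if (length(missing_lv)) {
    stop("height data lack eccentricity level(s): ",
         paste(format(missing_lv), collapse = ", "), call. = FALSE)
  }
  prior <- prior_spec("height", design)
  post <- sample_posterior("height", trials, prior, ...)
  nm <- paste0("sigma_", level_key(design$eccentricity_levels))
  pm <- colMeans(post$draws[, nm, drop = FALSE])
  mp <- post$map$theta[nm]
  names(pm) <- names(mp) <- level_key(design$eccentricity_levels)
  list(posterior_mean = pm, map = mp, posterior = post)
}

#' Accuracy of the Bayes-optimal observer for a given noise profile
#'
#' Simulates the Bayes observer with optimal parameters (`p_common = 0.5`,
#' no lapse) and the supplied noise profile on freshly generated
#' collinearity trials, `n_sim` per eccentricity level, and returns the
#' proportion of correct category reports per level with binomial SE.
#'
#' @param noise named vector of noise SDs per eccentricity level.
#' @param design the task design.
#' @param n_sim simulated trials per level (>= 1e4 recommended).
#' @param seed integer RNG seed.
#' @return data frame with `eccentricity`, `accuracy`, `se`, `n`.
#' @export
optimal_accuracy <- function(noise, design = make_default_design(),
                             n_sim = 1e5, seed = 1) {
  n_sim <- assert_count(n_sim, "n_sim")
  levels <- design$eccentricity_levels
  idx <- match_level(levels, as.numeric(names(noise)))
  seeds <- child_seeds(seed, 2L * length(levels))
  out <- data.frame(eccentricity = levels, accuracy = NA_real_,
                    se = NA_real_, n = n_sim)
  for (i in seq_along(levels)) {
    d1 <- collinearity_design(
      eccentricity_levels = levels[i], offset_sd = design$offset_sd,
      prior_collinear = design$prior_collinear)
    tr <- generate_collinearity_trials(d1, n_sim, seed = seeds[2 * i - 1])
    par <- observer_params("bayes", sigma_x = noise[idx[i]],
                           levels = levels[i], lapse = 0,
                           sigma_y = design$offset_sd, p_common = 0.5)
    tr <- simulate_responses(par, tr, seed = seeds[2 * i])
    correct <- (tr$response == "collinear") == (tr$category == "collinear")
    acc <- mean(correct)
    out$accuracy[i] <- acc
    out$se[i] <- sqrt(acc * (1 - acc) / n_sim)
  }
  out
}

#' Efficiency of observed behavior relative to the Bayes-optimal observer
#'
#' Overall efficiency is the overall observed proportion correct divided by
#' the optimal proportion correct, with the optimal accuracies weighted by
#' the observed trial counts per eccentricity level.
#'
#' @param trials responded collinearity-task trials with categories.
#' @param optimal output of [optimal_accuracy()] for the matching design.
#' @return a `cj_efficiency` list: per-level table and overall `efficiency`.
#' @export
efficiency <- function(trials, optimal) {
  validate_trials(trials, task = "collinearity", need_response = TRUE)
  correct <- (trials$response == "collinear") == (trials$category == "collinear")
  levels <- optimal$eccentricity
  idx <- match_level(trials$eccentricity, levels)
  nobs <- tabulate(idx, length(levels))
  if (any(nobs == 0)) stop("trials missing an eccentricity level of `optimal`",
                           call. = FALSE)
  obs_acc <- vapply(seq_along(levels), function(i) mean(correct[idx == i]),
                    numeric(1))
  overall_obs <- mean(correct)
  overall_opt <- sum(optimal$accuracy * nobs) / sum(nobs)
  structure(list(
    table = data.frame(eccentricity = levels, n = nobs,
                       observed = obs_acc, optimal = optimal$accuracy),
    observed_overall = overall_obs, optimal_overall = overall_opt,
    efficiency = overall_obs / overall_opt
  ), class = "cj_efficiency")
}

#' @export
print.cj_efficiency <- function(x, ...) {
  cat("Efficiency relative to the Bayes-optimal observer\n")
  print(transform(x$table, observed = round(observed, 4),
                  optimal = round(optimal, 4)), row.names = FALSE)
  cat(sprintf("overall: %.4f / %.4f = efficiency %.4f\n",
              x$observed_overall, x$optimal_overall, x$efficiency))
  invisible(x)
}

#' Posterior predictive psychometric curves
#'
#' Evaluates the analytic response probability under `n_draws` equally
#' spaced posterior draws, averages it within the offset bins of
#' [bin_psychometric()], and returns mean and SD bands per (eccentricity,
#' bin).
#'
#' @param post a `cj_posterior` for a collinearity-task model.
#' @param trials the trials to predict (stimuli are taken from here).
#' @param n_draws number of equally spaced posterior draws.
#' @param edges psychometric bin edges.
#' @return data frame with per (eccentricity, bin) rows: trial count `n`,
#'   predicted `mean` and `sd` across draws.
#' @export
posterior_predictive_curves <- function(post, trials, n_draws = 60,
                                        edges = default_offset_edges()) {
  stopifnot(inherits(post, "cj_posterior"))
  validate_trials(trials, task = "collinearity")
  n_draws <- assert_count(n_draws, "n_draws")
  S <- nrow(post$draws)
  take <- unique(round(seq(1, S, length.out = min(n_draws, S))))
  breaks <- offset_breaks(edges)
  bin <- cut(trials$y_left - trials$y_right, breaks = breaks, right = TRUE)
  ecc <- sort(unique(trials$eccentricity))
  cell <- interaction(factor(trials$eccentricity, levels = ecc), bin,
                      drop = FALSE)
  preds <- vapply(take, function(s) {
    par <- vector_to_params(post$prior, post$draws[s, ])
    p <- p_collinear_response(par, trials)
    as.vector(tapply(p, cell, mean, default = NA_real_))
  }, numeric(length(levels(cell))))
  grid <- expand.grid(eccentricity = ecc, bin = levels(bin),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # interaction() varies its first factor fastest, matching this grid order
  grid$n <- as.vector(table(cell))
  grid$mean <- rowMeans(preds)
  grid$sd <- apply(preds, 1, sd)
  if (length(take) == 1L) grid$sd <- 0
  grid
}

#' Parameter recovery harness
#'
#' Simulates datasets from known parameters, refits them, and reports
#' per-parameter truth, estimate, bias and error across replicates. With
#' `method = "mcmc"` also reports whether each replicate's central 95%
#' credible interval covers the truth.
#'
#' @param params generating [observer_params()].
#' @param design task design used to generate trials.
#' @param n_trials trials per replicate.
#' @param n_replicates number of simulate-fit replicates.
#' @param method `"map"` (point fit) or `"mcmc"`.
#' @param seed integer RNG seed.
#' @param ... passed to [map_fit()] or [sample_posterior()].
#' @return a `cj_recovery` data frame (replicate x parameter rows).
#' @export
parameter_recovery <- function(params, design = make_default_design(),
                               n_trials = 2400, n_replicates = 4,
                               method = c("map", "mcmc"), seed = 1, ...) {
  stopifnot(inherits(params, "observer_params"))
  method <- match.arg(method)
  prior <- prior_spec(params$model, design)
  truth <- params_to_vector(prior, params)
  seeds <- matrix(child_seeds(seed, 3L * n_replicates), ncol = 3L)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    gen <- if (params$model == "height") generate_height_trials else
      generate_collinearity_trials
    tr <- gen(design, n_trials, seed = seeds[r, 1],
              subject_id = paste0("rep", r))
    tr <- simulate_responses(params, tr, seed = seeds[r, 2])
    if (method == "map") {
      fit <- map_fit(params$model, tr, prior, seed = seeds[r, 3], ...)
      est <- fit$theta
      lo <- hi <- rep(NA_real_, length(est))
    } else {
      post <- sample_posterior(params$model, tr, prior, seed = seeds[r, 3],
                               ...)
      est <- colMeans(post$draws)
      lo <- apply(post$draws, 2, quantile, 0.025)
      hi <- apply(post$draws, 2, quantile, 0.975)
    }
    rows[[r]] <- data.frame(replicate = r, parameter = prior$name,
                            truth = unname(truth), estimate = unname(est),
                            ci_lower = unname(lo), ci_upper = unname(hi),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$error <- out$estimate - out$truth
  class(out) <- c("cj_recovery", "data.frame")
  out
}

#' Model recovery harness
#'
#' For each generating model, simulates a cohort of synthetic subjects,
#' fits every candidate model by MCMC, scores each fit by PSIS-LOO, and
#' tabulates the confusion matrix of winning models plus the mean LOO of
#' each fitted model per cohort.
#'
#' @param param_sets named list (one per generating model) of
#'   [observer_params()].
#' @param design task design.
#' @param n_subjects synthetic subjects per cohort.
#' @param n_trials trials per subject.
#' @param fit_models models to fit to every dataset; defaults to the
#'   generating set.
#' @param seed integer RNG seed.
#' @param fit_settings optional named list (by fitted model) of argument
#'   lists that override `...` for that model's [sample_posterior()] call,
#'   e.g. longer chains for cheap models.
#' @param ... passed to [sample_posterior()] (reduced chain settings are
#'   typical here).
#' @return a `cj_model_recovery` list: `confusion` (generator x winner
#'   counts), `mean_loo` (generator x fitted model), and the full `loo`
#'   array.
#' @export
model_recovery <- function(param_sets, design = make_default_design(),
                           n_subjects = 8, n_trials = 2400,
                           fit_models = names(param_sets), seed = 1,
                           fit_settings = list(), ...) {
  stopifnot(is.list(param_sets), length(names(param_sets)) ==
              length(param_sets))
  gens <- names(param_sets)
  n_subjects <- assert_count(n_subjects, "n_subjects")
  loo_arr <- array(NA_real_, dim = c(length(gens), n_subjects,
                                     length(fit_models)),
                   dimnames = list(gens, NULL, fit_models))
  seeds <- array(child_seeds(seed, length(gens) * n_subjects * 3L),
                 dim = c(length(gens), n_subjects, 3L))
  for (g in seq_along(gens)) {
    for (s in seq_len(n_subjects)) {
      tr <- generate_collinearity_trials(design, n_trials,
                                         seed = seeds[g, s, 1],
                                         subject_id = sprintf("%s_%02d",
                                                              gens[g], s))
      tr <- simulate_responses(param_sets[[g]], tr, seed = seeds[g, s, 2])
      for (fm in seq_along(fit_models)) {
        args <- utils::modifyList(
          list(model = fit_models[fm], trials = tr,
               seed = seeds[g, s, 3] + fm, ...),
          as.list(fit_settings[[fit_models[fm]]]))
        post <- do.call(sample_posterior, args)
        loo_arr[g, s, fm] <- psis_loo(post)$loo
      }
    }
  }
  winners <- apply(loo_arr, c(1, 2), function(v) fit_models[which.max(v)])
  confusion <- t(vapply(seq_along(gens), function(g) {
    tabulate(factor(winners[g, ], levels = fit_models),
             length(fit_models))
  }, integer(length(fit_models))))
  dimnames(confusion) <- list(generator = gens, winner = fit_models)
  mean_loo <- apply(loo_arr, c(1, 3), mean)
  structure(list(confusion = confusion, mean_loo = mean_loo, loo = loo_arr),
            class = "cj_model_recovery")
}

#' @export
print.cj_model_recovery <- function(x, ...) {
  cat("Model recovery confusion matrix (PSIS-LOO winners)\n")
  print(x$confusion)
  cat("\nMean LOO by generator (rows) and fitted model (columns)\n")
  print(round(x$mean_loo, 1))
  invisible(x)
}
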