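# Posterior inference: likelihood closure with coordinate-wise caching,
# MAP estimation, and coordinate-wise slice sampling.

# Likelihood closure. Coordinate-wise samplers change one free parameter at
# a time, so the per-trial rule probabilities are cached and only the trials
# affected by the changed parameter are recomputed: lapse touches nothing,
# a noise SD touches its level's trials, everything else touches all trials.
# All static per-trial quantities are precomputed; the hot path never touches
# the data frame.
make_loglik <- function(prior, trials, n_nodes = 25L) {
  validate_trials(trials, need_response = TRUE)
  model <- attr(prior, "model")
  levels <- attr(prior, "levels")
  sigma_y <- attr(prior, "sigma_y")
  con_noise <- attr(prior, "constrained_noise")
  n <- nrow(trials)
  is_height_task <- trials$task == "height"
  if (model == "height" && any(!is_height_task)) {
    stop("the height model fits height-task trials only", call. = FALSE)
  }
  if (model != "height" && any(is_height_task)) {
    stop(sprintf("model '%s' fits collinearity-task trials only", model),
         call. = FALSE)
  }
  lvl <- match_level(trials$eccentricity, levels)
  nl <- length(levels)
  delta <- trials$y_left - trials$y_right
  mcoord <- (trials$y_left + trials$y_right) / 2
  ecc <- trials$eccentricity
  gl <- gauss_legendre(n_nodes)
  glu <- gauss_legendre(15L)
  resp_pos <- if (model == "height") {
    trials$response == "right_higher"
  } else {
    trials$response == "collinear"
  }
  # parameter positions in theta
  pos <- function(nm) match(nm, prior$name)
  i_sigma <- if (is.null(con_noise)) {
    pos(paste0("sigma_", level_key(levels)))
  } else NULL
  fixed_sigma <- if (is.null(con_noise)) NULL else {
    unname(con_noise[match(levels, as.numeric(names(con_noise)))])
  }
  i_lambda <- pos("lambda")
  sig_of <- function(theta) {
    if (is.null(i_sigma)) fixed_sigma else unname(theta[i_sigma])
  }
  # lagged level-index matrix for the history model (lag 0..4, per trial,
  # padded with the current trial within each subject x session)
  if (model == "history") {
    lag_idx <- matrix(seq_len(n), n, 5L)
    key <- interaction(trials$subject_id, trials$session, drop = TRUE)
    for (g in levels(key)) {
      rows <- which(key == g)
      ord <- rows[order(trials$block[rows], trials$trial_index[rows])]
      for (k in 1:4) {
        if (length(ord) > k) {
          lag_idx[ord[(k + 1):length(ord)], k + 1L] <-
            ord[seq_len(length(ord) - k)]
        }
      }
    }
  }
  # rule probability for trial subset idx given free parameters theta
  rule <- function(theta, idx) {
    sig <- sig_of(theta)
    s_t <- sig[lvl[idx]]
    if (model == "height") {
      return(pnorm((trials$y_right[idx] - trials$y_left[idx]) /
                     (sqrt(2) * s_t)))
    }
    su <- sqrt(2) * s_t
    fam <- model_family(model)
    if (fam == "threshold") {
      kap <- switch(model,
        fixed = rep_len(theta[[pos("kappa")]], length(idx)),
        lin = theta[[pos("kappa0")]] + theta[[pos("kappa1")]] * s_t,
        nonparametric = unname(theta[pos(paste0("kappa_",
                                               level_key(levels)))])[lvl[idx]],
        history = {
          w <- unname(theta[pos(paste0("w", 0:4))])
          sig_all <- sig[lvl]
          k <- rep_len(theta[[pos("kappa0")]], length(idx))
          for (l in 1:5) k <- k + w[l] * sig_all[lag_idx[idx, l]]
          k
        })
      kap <- pmax(kap, 0)
      return(pnorm((kap - delta[idx]) / su) - pnorm((-kap - delta[idx]) / su))
    }
    # Bayes family: per-level boundary coefficients with assumed quantities
    sig_a <- if (model == "noise_mismatch") {
      theta[[pos("assumed_intercept")]] + theta[[pos("assumed_slope")]] * sig
    } else sig
    sy_a <- if (model %in% c("width_mismatch", "hybrid_dn_width")) {
      theta[[pos("sigma_y_assumed")]]
    } else sigma_y
    p_c <- if (model == "noise_mismatch") 0.5 else theta[[pos("p_common")]]
    cf <- boundary_coefficients(sig_a, sy_a, p_c)
    tau <- s_t / sqrt(2)
    if (fam == "boundary") {
      .cpp_p_boundary(mcoord[idx], delta[idx], ecc[idx],
                      rep_len(cf$K, nl)[lvl[idx]], rep_len(cf$A, nl)[lvl[idx]],
                      rep_len(cf$cv, nl)[lvl[idx]], tau, su, gl$x, gl$w)
    } else {
      .cpp_p_decision_noise(mcoord[idx], delta[idx], ecc[idx],
                            rep_len(cf$K, nl)[lvl[idx]],
                            rep_len(cf$A, nl)[lvl[idx]],
                            rep_len(cf$cv, nl)[lvl[idx]], tau, su,
                            rep_len(theta[[pos("sigma_d")]], length(idx)),
                            gl$x, gl$w, glu$x, glu$w)
    }
  }
  affected <- lapply(seq_len(nrow(prior)), function(j) {
    switch(prior$scope[j],
           lapse = integer(0),
           level = which(lvl == match_level(prior$level[j], levels)),
           all = seq_len(n))
  })
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  cache$r <- NULL
  function(theta) {
    theta <- setNames(as.numeric(theta), prior$name)
    if (is.null(cache$theta)) {
      idx <- seq_len(n)
    } else {
      changed <- which(theta != cache$theta)
      idx <- if (length(changed) == 0L) integer(0) else {
        sets <- affected[changed]
        lens <- vapply(sets, length, integer(1))
        if (any(lens == n)) seq_len(n) else unique(unlist(sets))
      }
    }
    r <- if (is.null(cache$r)) numeric(n) else cache$r
    if (length(idx)) r[idx] <- pmin(pmax(rule(theta, idx), 0), 1)
    cache$theta <- theta
    cache$r <- r
    lambda <- theta[[i_lambda]]
    p_resp <- lambda / 2 + (1 - lambda) * r
    pw <- ifelse(resp_pos, log(p_resp), log1p(-p_resp))
    list(total = sum(pw), pointwise = pw)
  }
}

# bounded optimization in sampling coordinates: Nelder-Mead with an
# out-of-bounds penalty, then an L-BFGS-B polish
optim_bounded <- function(fn, start, lower, upper, maxit = 400) {
  penalized <- function(x) {
    if (any(x < lower) || any(x > upper)) return(1e10)
    v <- fn(x)
    if (!is.finite(v)) 1e10 else v
  }
  if (length(start) == 1L) {
    return(optim(start, penalized, method = "Brent", lower = lower,
                 upper = upper, control = list(maxit = maxit)))
  }
  res <- optim(start, penalized, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-10))
  polish <- tryCatch(
    optim(res$par, penalized, method = "L-BFGS-B",
          lower = lower, upper = upper,
          control = list(maxit = 25, factr = 1e7)),
    error = function(e) NULL)
  if (!is.null(polish) && is.finite(polish$value) &&
      polish$value < res$value) res <- polish
  res
}

#' Maximum a posteriori / maximum likelihood point estimate
#'
#' Runs `n_starts` bounded optimizations of the log posterior (equal to the
#' log likelihood up to a constant, since priors are uniform in the sampling
#' coordinates) and returns the best. The first start is the midpoint of the
#' transformed bounds, the rest are drawn uniformly within them.
#' Deterministic given `seed`.
#'
#' @param model model identifier, see [cj_models()].
#' @param trials responded trial table.
#' @param prior a [prior_spec()]; defaults to the model's standard bounds.
#' @param n_starts number of optimization starts.
#' @param seed integer RNG seed.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param n_nodes quadrature nodes (Bayes family likelihoods).
#' @return a `cj_map` list: `theta` (named natural-scale estimate),
#'   `loglik`, `model`, and per-start diagnostics.
#' @export
map_fit <- function(model, trials, prior = NULL, n_starts = 3, seed = 1,
                    maxit = 400, n_nodes = 25L) {
  model <- match_model(model)
  if (is.null(prior)) prior <- prior_spec(model)
  ll <- make_loglik(prior, trials, n_nodes = n_nodes)
  b <- sampling_bounds(prior)
  free <- b$upper - b$lower > 1e-12  # equal bounds pin the parameter
  base <- b$lower
  neg <- function(t_free) {
    t_all <- base
    t_all[free] <- t_free
    -ll(from_sampling(prior, t_all))$total
  }
  n_starts <- assert_count(n_starts, "n_starts")
  nf <- sum(free)
  if (nf == 0L) {
    theta <- setNames(from_sampling(prior, base), prior$name)
    return(structure(list(theta = theta, loglik = -neg(numeric(0)),
                          model = model, prior = prior,
                          start_values = NA_real_, convergence = 0L),
                     class = "cj_map"))
  }
  starts <- with_seed(seed, {
    s <- matrix(runif(n_starts * nf, b$lower[free], b$upper[free]),
                nrow = n_starts, byrow = TRUE)
    s[1, ] <- (b$lower[free] + b$upper[free]) / 2
    s
  })
  fits <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    fits[[i]] <- tryCatch(optim_bounded(neg, starts[i, ], b$lower[free],
                                        b$upper[free], maxit = maxit),
                          error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all optimization starts failed", call. = FALSE)
  values <- vapply(fits[ok], `[[`, numeric(1), "value")
  best <- fits[ok][[which.min(values)]]
  t_all <- base
  t_all[free] <- best$par
  theta <- setNames(from_sampling(prior, t_all), prior$name)
  structure(list(theta = theta, loglik = -best$value, model = model,
                 prior = prior, start_values = values,
                 convergence = best$convergence),
            class = "cj_map")
}

# one coordinate-wise slice-sampling sweep (Neal 2003, step-out + shrinkage)
slice_sweep <- function(f, x, fx, widths, lower, upper, max_shrink = 1000) {
  for (j in seq_along(x)) {
    if (upper[j] - lower[j] <= 1e-12) next  # pinned parameter
    y <- fx - rexp(1)
    w <- widths[j]
    L <- max(x[j] - w * runif(1), lower[j])
    R <- min(L + w, upper[j])
    fL <- f(replace(x, j, L))
    while (L > lower[j] && fL > y) {
      L <- max(L - w, lower[j])
      fL <- f(replace(x, j, L))
    }
    fR <- f(replace(x, j, R))
    while (R < upper[j] && fR > y) {
      R <- min(R + w, upper[j])
      fR <- f(replace(x, j, R))
    }
    for (it in seq_len(max_shrink)) {
      x1 <- runif(1, L, R)
      f1 <- f(replace(x, j, x1))
      if (f1 >= y) {
        x[j] <- x1
        fx <- f1
        break
      }
      if (x1 < x[j]) L <- x1 else R <- x1
      if (it == max_shrink) stop("slice sampler failed to shrink",
                                 call. = FALSE)
    }
  }
  list(x = x, fx = fx)
}

#' Sample the posterior by coordinate-wise slice sampling
#'
#' Chains are initialized at the MAP estimate (jittered per chain) and run
#' coordinate-wise slice sampling with step-out in the sampling coordinates
#' (log space for scale parameters, where the uniform-in-log prior is flat).
#' Per-trial pointwise log-likelihoods are stored for every retained draw so
#' that [psis_loo()] can be computed without re-evaluating the model.
#'
#' @inheritParams map_fit
#' @param n_chains number of chains (>= 1; >= 2 for [gelman_rubin()]).
#' @param n_samples retained draws per chain (after burn-in).
#' @param burn_in discarded initial draws per chain.
#' @param map optional precomputed [map_fit()] result to initialize from.
#' @param n_starts optimization starts for the internal MAP fit.
#' @return a `cj_posterior` list: merged `draws` (matrix, natural scale),
#'   per-chain draws, `log_lik` per draw, `pointwise` log-likelihood matrix
#'   (draws x trials), `rhat` per parameter, and the inputs needed to
#'   reproduce the run.
#' @export
sample_posterior <- function(model, trials, prior = NULL, n_chains = 3,
                             n_samples = 2000, burn_in = 500, seed = 1,
                             map = NULL, n_starts = 2, n_nodes = 25L,
                             maxit = 300) {
  model <- match_model(model)
  if (is.null(prior)) prior <- prior_spec(model)
  n_chains <- assert_count(n_chains, "n_chains")
  n_samples <- assert_count(n_samples, "n_samples")
  burn_in <- assert_count(burn_in, "burn_in", min = 0L)
  if (nrow(trials) == 0L) stop("`trials` is empty", call. = FALSE)
  seeds <- child_seeds(seed, n_chains + 1L)
  if (is.null(map)) {
    map <- map_fit(model, trials, prior, n_starts = n_starts,
                   seed = seeds[n_chains + 1L], maxit = maxit,
                   n_nodes = n_nodes)
  }
  b <- sampling_bounds(prior)
  widths <- (b$upper - b$lower) / 10
  t_map <- to_sampling(prior, map$theta)
  npar <- nrow(prior)
  chain_draws <- vector("list", n_chains)
  chain_ll <- vector("list", n_chains)
  chain_pw <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    ll <- make_loglik(prior, trials, n_nodes = n_nodes)
    pw_cache <- new.env(parent = emptyenv())
    f <- function(t_theta) {
      res <- ll(from_sampling(prior, t_theta))
      pw_cache$pw <- res$pointwise
      res$total
    }
    with_seed(seeds[ch], {
      x <- pmin(pmax(t_map + rnorm(npar, 0, widths / 50), b$lower), b$upper)
      fx <- f(x)
      if (!is.finite(fx)) {
        stop("non-finite posterior at chain initialization", call. = FALSE)
      }
      draws <- matrix(NA_real_, n_samples, npar,
                      dimnames = list(NULL, prior$name))
      llv <- numeric(n_samples)
      pwm <- matrix(NA_real_, n_samples, nrow(trials))
      w_ch <- widths
      burn_draws <- if (burn_in >= 20L) {
        matrix(NA_real_, burn_in, npar)
      } else NULL
      for (it in seq_len(burn_in + n_samples)) {
        st <- slice_sweep(f, x, fx, w_ch, b$lower, b$upper)
        x <- st$x
        fx <- st$fx
        if (!is.null(burn_draws) && it <= burn_in) burn_draws[it, ] <- x
        if (it == burn_in && !is.null(burn_draws)) {
          # adapt slice widths to the posterior scale seen during burn-in
          s <- apply(burn_draws[max(1, burn_in - 200):burn_in, , drop = FALSE],
                     2, sd)
          ok <- is.finite(s) & s > 0
          w_ch[ok] <- pmin(pmax(3 * s[ok], widths[ok] / 50), widths[ok])
        }
        if (it > burn_in) {
          k <- it - burn_in
          draws[k, ] <- from_sampling(prior, x)
          llv[k] <- fx
          pwm[k, ] <- pw_cache$pw
        }
      }
      chain_draws[[ch]] <- draws
      chain_ll[[ch]] <- llv
      chain_pw[[ch]] <- pwm
    })
  }
  rhat <- tryCatch(gelman_rubin(chain_draws), error = function(e) {
    setNames(rep(NA_real_, npar), prior$name)
  })
  structure(list(
    model = model, draws = do.call(rbind, chain_draws),
    chain_draws = chain_draws, log_lik = unlist(chain_ll),
    pointwise = do.call(rbind, chain_pw), rhat = rhat,
    n_chains = n_chains, n_samples = n_samples, burn_in = burn_in,
    seed = seed, prior = prior, map = map, n_trials = nrow(trials)
  ), class = "cj_posterior")
}

#' @export
print.cj_posterior <- function(x, ...) {
  cat(sprintf("Posterior for model '%s': %d chains x %d draws (burn-in %d), %d trials\n",
              x$model, x$n_chains, x$n_samples, x$burn_in, x$n_trials))
  summ <- rbind(mean = colMeans(x$draws), sd = apply(x$draws, 2, sd),
                rhat = x$rhat)
  print(round(summ, 4))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction statistic
#'
#' Classic between/within-chain variance ratio
#' \eqn{\hat R = \sqrt{(\frac{n-1}{n} W + \frac{B}{n}) / W}} per parameter.
#'
#' @param chains a `cj_posterior` or a list of draws matrices
#'   (iterations x parameters), one per chain.
#' @return named vector of \eqn{\hat R} values.
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains, "cj_posterior")) chains <- chains$chain_draws
  if (!is.list(chains) || length(chains) < 2L) {
    stop("need at least 2 chains", call. = FALSE)
  }
  n <- nrow(chains[[1]])
  if (n < 10L) stop("need at least 10 draws per chain", call. = FALSE)
  r <- vapply(seq_len(ncol(chains[[1]])), function(j) {
    xs <- lapply(chains, function(m) m[, j])
    W <- mean(vapply(xs, var, numeric(1)))
    if (W == 0) stop("zero within-chain variance: R-hat undefined",
                     call. = FALSE)
    B <- n * var(vapply(xs, mean, numeric(1)))
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  setNames(r, colnames(chains[[1]]))
}
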