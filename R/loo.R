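# PSIS-LOO cross-validation and AIC.

# Generalized Pareto fit to exceedances (Zhang & Stephens 2009 profile
# posterior-mean estimate, with the weak k-prior used by common PSIS
# implementations for stability).
gpd_fit <- function(x) {
  n <- length(x)
  x <- sort(x)
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  q1 <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (prior_bs * q1)
  # xi(theta): conditional MLE of the (usual-convention) shape
  xi_j <- vapply(theta, function(th) mean(log1p(-th * x)), numeric(1))
  l_j <- n * (log(-theta / xi_j) - xi_j - 1)
  w <- exp(l_j - max(l_j))
  w <- w / sum(w)
  th_hat <- sum(theta * w)
  k <- mean(log1p(-th_hat * x))
  sigma <- -k / th_hat
  k_reg <- (n * k + 10 * 0.5) / (n + 10)  # weakly informative prior on k
  list(k = k_reg, k_raw = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smooth one vector of log importance ratios; returns normalized-ish
# log weights (max 0) and the tail-shape diagnostic k
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5 || length(unique(lw)) < 5) {
    return(list(lw = lw, k = NA_real_))
  }
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cut_lw <- lw[ord[S - M]]
  exc <- exp(lw[tail_ids]) - exp(cut_lw)
  if (all(exc <= 0)) return(list(lw = lw, k = NA_real_))
  fit <- gpd_fit(exc[exc > 0])
  qq <- qgpd((seq_len(M) - 0.5) / M, fit$k, fit$sigma) + exp(cut_lw)
  # assign smoothed quantiles in the order of the raw tail weights
  lw[tail_ids[order(lw[tail_ids])]] <- log(qq)
  lw <- pmin(lw, 0)  # truncate at the largest raw weight
  list(lw = lw - max(lw), k = fit$k)
}

#' PSIS-LOO cross-validation score
#'
#' Estimates the Bayesian leave-one-out predictive score from full-posterior
#' draws: for trial \eqn{i} the raw importance ratios
#' \eqn{1/p(C_i|\theta^{(s)})} are Pareto-smoothed in their upper tail (the
#' largest \eqn{M = \min(S/5, 3\sqrt{S})} weights are replaced by
#' generalized-Pareto quantiles and truncated at the raw maximum), and the
#' pointwise contribution is the log weighted mean likelihood. Trials whose
#' Pareto shape exceeds 0.7 are flagged as unreliable.
#'
#' @param x a `cj_posterior` or a pointwise log-likelihood matrix
#'   (draws x trials) with at least 100 draws.
#' @return a `cj_loo` list: `loo` (sum of pointwise terms), `pointwise`,
#'   `k` (Pareto shape per trial), `se` (from the pointwise-term variance),
#'   `n_bad_k` (trials with k > 0.7).
#' @export
psis_loo <- function(x) {
  ll <- if (inherits(x, "cj_posterior")) x$pointwise else as.matrix(x)
  S <- nrow(ll)
  N <- ncol(ll)
  if (S < 100L) stop("need at least 100 posterior draws", call. = FALSE)
  pointwise <- numeric(N)
  kvec <- numeric(N)
  for (i in seq_len(N)) {
    sm <- psis_smooth(-ll[, i])
    pointwise[i] <- log_sum_exp(sm$lw + ll[, i]) - log_sum_exp(sm$lw)
    kvec[i] <- sm$k
  }
  structure(list(loo = sum(pointwise), pointwise = pointwise, k = kvec,
                 se = sqrt(N * var(pointwise)),
                 n_bad_k = sum(kvec > 0.7, na.rm = TRUE), n_draws = S),
            class = "cj_loo")
}

#' @export
print.cj_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO: %.2f (SE %.2f) over %d trials, %d draws; k > 0.7 on %d trial(s)\n",
              x$loo, x$se, length(x$pointwise), x$n_draws, x$n_bad_k))
  invisible(x)
}

#' Akaike information criterion
#'
#' `aic()` returns \eqn{-2\,\hat\ell + 2k}; `aic_evidence()` returns
#' \eqn{-\mathrm{AIC}/2}, the scale comparable to a LOO score for rank
#' checks.
#'
#' @param max_loglik maximized log-likelihood.
#' @param n_params number of free parameters.
#' @return a scalar.
#' @export
aic <- function(max_loglik, n_params) {
  -2 * max_loglik + 2 * n_params
}

#' @rdname aic
#' @export
aic_evidence <- function(max_loglik, n_params) {
  -aic(max_loglik, n_params) / 2
}
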