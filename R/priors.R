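#' Prior specification (parameter bounds) for a model
#'
#' All parameters carry uniform priors within bounds; scale parameters
#' (noise SDs, decision noise, assumed width) are sampled uniformly in log
#' space. Defaults: \eqn{\sigma_x \in [0.05, 10]} dva (log),
#' \eqn{\lambda \in [0, 0.3]}, `p_common` in \eqn{[0.1, 0.9]},
#' criterion-type parameters in \eqn{[-5, 5]} dva (the effective criterion
#' is clipped at 0), \eqn{\sigma_d \in [0.01, 20]} (log), assumed width in
#' \eqn{[0.05, 5]} dva (log), assumed-noise mapping intercept in
#' \eqn{[0, 5]} and slope in \eqn{[0.05, 3]}.
#'
#' Passing `constrained_noise` (a noise profile, e.g. imported from the
#' height task via [import_height_noise()]) removes the noise SDs from the
#' free parameters and fixes them, leaving the constrained variants with
#' 2 (`fixed`, `bayes`) or 3 (`lin`) free parameters.
#'
#' @param model model identifier, see [cj_models()].
#' @param design a [collinearity_design()]; supplies the eccentricity levels
#'   and the known offset width `sigma_y`.
#' @param constrained_noise optional named vector of noise SDs per level;
#'   fixes the noise profile instead of fitting it.
#' @return a `cj_prior` data frame with columns `name`, `lower`, `upper`,
#'   `log_scale`, `scope`, `level`.
#' @export
prior_spec <- function(model, design = make_default_design(),
                       constrained_noise = NULL) {
  model <- match_model(model)
  levels <- design$eccentricity_levels
  row <- function(name, lower, upper, log_scale = FALSE, scope = "all",
                  level = NA_real_) {
    data.frame(name = name, lower = lower, upper = upper,
               log_scale = log_scale, scope = scope, level = level,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  if (is.null(constrained_noise)) {
    noise_scope <- if (model == "history") "all" else "level"
    for (l in levels) {
      rows <- c(rows, list(row(paste0("sigma_", format(l)), 0.05, 10,
                               log_scale = TRUE, scope = noise_scope,
                               level = l)))
    }
  } else {
    nm <- as.numeric(names(constrained_noise))
    if (length(nm) == 0 || anyNA(nm)) {
      stop("`constrained_noise` must be named by eccentricity level",
           call. = FALSE)
    }
    match_level(levels, nm)  # errors if a design level is missing
  }
  rows <- c(rows, list(row("lambda", 0, 0.3, scope = "lapse")))
  rows <- c(rows, switch(model,
    fixed = list(row("kappa", -5, 5)),
    bayes = list(row("p_common", 0.1, 0.9)),
    lin = list(row("kappa0", -5, 5), row("kappa1", -5, 5)),
    history = c(list(row("kappa0", -5, 5)),
                lapply(0:4, function(k) row(paste0("w", k), -5, 5))),
    noise_mismatch = list(row("assumed_intercept", 0, 5),
                          row("assumed_slope", 0.05, 3)),
    width_mismatch = list(row("p_common", 0.1, 0.9),
                          row("sigma_y_assumed", 0.05, 5, log_scale = TRUE)),
    bayes_dn = list(row("p_common", 0.1, 0.9),
                    row("sigma_d", 0.01, 20, log_scale = TRUE)),
    hybrid_dn_width = list(row("p_common", 0.1, 0.9),
                           row("sigma_y_assumed", 0.05, 5, log_scale = TRUE),
                           row("sigma_d", 0.01, 20, log_scale = TRUE)),
    nonparametric = lapply(levels, function(l) {
      row(paste0("kappa_", format(l)), -5, 5, scope = "level", level = l)
    }),
    height = list()
  ))
  out <- do.call(rbind, rows)
  # equal bounds pin a parameter at that value; reversed bounds are an error
  if (any(out$lower > out$upper)) stop("invalid bounds", call. = FALSE)
  if (any(out$log_scale & out$lower <= 0)) {
    stop("scale parameters need positive lower bounds", call. = FALSE)
  }
  attr(out, "model") <- model
  attr(out, "levels") <- levels
  attr(out, "sigma_y") <- design$offset_sd
  attr(out, "constrained_noise") <- constrained_noise
  class(out) <- c("cj_prior", "data.frame")
  out
}

# transformed (sampling) coordinates: log for scale parameters
to_sampling <- function(prior, theta) {
  out <- theta
  out[prior$log_scale] <- log(theta[prior$log_scale])
  out
}
from_sampling <- function(prior, t_theta) {
  out <- t_theta
  out[prior$log_scale] <- exp(t_theta[prior$log_scale])
  out
}
sampling_bounds <- function(prior) {
  list(lower = to_sampling(prior, prior$lower),
       upper = to_sampling(prior, prior$upper))
}

# assemble an observer_params from a named free-parameter vector
vector_to_params <- function(prior, theta) {
  model <- attr(prior, "model")
  levels <- attr(prior, "levels")
  con <- attr(prior, "constrained_noise")
  th <- setNames(as.numeric(theta), prior$name)
  sigma_x <- if (is.null(con)) {
    unname(th[paste0("sigma_", level_key(levels))])
  } else {
    unname(con[match(levels, as.numeric(names(con)))])
  }
  args <- list(model = model, sigma_x = sigma_x, levels = levels,
               lapse = unname(th[["lambda"]]), sigma_y = attr(prior, "sigma_y"))
  extra <- switch(model,
    fixed = list(kappa = max(th[["kappa"]], 0)),
    bayes = list(p_common = th[["p_common"]]),
    lin = list(kappa0 = th[["kappa0"]], kappa1 = th[["kappa1"]]),
    history = list(kappa0 = th[["kappa0"]],
                   history_weights = unname(th[paste0("w", 0:4)])),
    noise_mismatch = list(assumed_intercept = th[["assumed_intercept"]],
                          assumed_slope = th[["assumed_slope"]]),
    width_mismatch = list(p_common = th[["p_common"]],
                          sigma_y_assumed = th[["sigma_y_assumed"]]),
    bayes_dn = list(p_common = th[["p_common"]], sigma_d = th[["sigma_d"]]),
    hybrid_dn_width = list(p_common = th[["p_common"]],
                           sigma_y_assumed = th[["sigma_y_assumed"]],
                           sigma_d = th[["sigma_d"]]),
    nonparametric = list(kappa_levels = unname(th[paste0("kappa_",
                                                         level_key(levels))])),
    height = list()
  )
  do.call(observer_params, c(args, extra))
}

params_to_vector <- function(prior, params) {
  levels <- attr(prior, "levels")
  vals <- c()
  for (nm in prior$name) {
    v <- if (startsWith(nm, "sigma_") &&
             nm %in% paste0("sigma_", level_key(levels))) {
      params$sigma_x[match(nm, paste0("sigma_", level_key(levels)))]
    } else if (nm == "lambda") params$lapse
    else if (nm == "p_common") params$p_common
    else if (nm == "kappa") params$kappa
    else if (nm == "kappa0") params$kappa0
    else if (nm == "kappa1") params$kappa1
    else if (nm %in% paste0("w", 0:4)) {
      params$history_weights[match(nm, paste0("w", 0:4))]
    } else if (nm == "assumed_intercept") params$assumed_intercept
    else if (nm == "assumed_slope") params$assumed_slope
    else if (nm == "sigma_y_assumed") params$sigma_y_assumed
    else if (nm == "sigma_d") params$sigma_d
    else if (startsWith(nm, "kappa_")) {
      params$kappa_levels[match(nm, paste0("kappa_", level_key(levels)))]
    } else stop("unknown parameter ", nm, call. = FALSE)
    vals <- c(vals, v)
  }
  setNames(vals, prior$name)
}
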