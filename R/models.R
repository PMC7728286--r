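#' Observer model registry
#'
#' Ten decision models are supported. All share an eccentricity-indexed
#' measurement noise profile \eqn{\sigma_x(y)} and a lapse rate
#' \eqn{\lambda}; the remaining parameters differ by model:
#'
#' * `fixed` - report "collinear" when `|x_L - x_R| <= kappa`, an
#'   uncertainty-independent criterion.
#' * `bayes` - report "collinear" when the log posterior ratio
#'   \eqn{d^* \ge 0}; free prior `p_common`.
#' * `lin` - linear heuristic criterion `kappa0 + kappa1 * sigma_x(y)`.
#' * `history` - Lin extended with the noise of up to four previous trials,
#'   each with its own weight.
#' * `noise_mismatch` - Bayes computing with assumed noise
#'   `a + b * sigma_x(y)` instead of the true noise; `p_common` fixed at 0.5.
#' * `width_mismatch` - Bayes computing with an assumed offset-distribution
#'   width `sigma_y_assumed`.
#' * `bayes_dn` - Bayes with Gaussian decision noise `sigma_d` on \eqn{d^*}.
#' * `hybrid_dn_width` - width mismatch plus decision noise.
#' * `nonparametric` - one free criterion per eccentricity level.
#' * `height` - height judgment rule: report "right higher" when
#'   `x_R > x_L` (noise profile + lapse only).
#'
#' @return `cj_models()` returns the model identifiers.
#' @export
cj_models <- function() {
  c("fixed", "bayes", "lin", "history", "noise_mismatch", "width_mismatch",
    "bayes_dn", "hybrid_dn_width", "nonparametric", "height")
}

match_model <- function(model) {
  match.arg(tolower(model), cj_models())
}

# which model families share a response-probability path
model_family <- function(model) {
  switch(model,
         fixed = , lin = , history = , nonparametric = "threshold",
         bayes = , noise_mismatch = , width_mismatch = "boundary",
         bayes_dn = , hybrid_dn_width = "decision_noise",
         height = "height")
}

#' Construct observer parameters
#'
#' Bundles a model identifier with that model's free parameters plus the
#' offset-distribution width `sigma_y` known from the task design. Only the
#' fields relevant to `model` are used; supplying an irrelevant field is an
#' error. See [cj_models()] for the parameter each model takes.
#'
#' @param model model identifier, see [cj_models()].
#' @param sigma_x measurement noise SDs (dva), one per eccentricity level;
#'   a named vector or one matching `levels`.
#' @param levels eccentricity levels (dva) that `sigma_x` refers to.
#' @param lapse lapse rate \eqn{\lambda \in [0, 1]}: probability of a
#'   stimulus-independent uniform response.
#' @param sigma_y offset-distribution SD assumed known to Bayes-family
#'   observers (from the design).
#' @param p_common prior probability of the collinear category (Bayes family).
#' @param kappa fixed criterion (dva), `fixed` model.
#' @param kappa0,kappa1 intercept and slope of the linear criterion (`lin`,
#'   and `kappa0` for `history`).
#' @param history_weights five weights for \eqn{\sigma_x} of the current and
#'   four previous trials (`history`).
#' @param assumed_intercept,assumed_slope coefficients of the assumed-noise
#'   mapping `sigma_assumed = a + b * sigma_x(y)` (`noise_mismatch`).
#' @param sigma_y_assumed assumed offset width (`width_mismatch`,
#'   `hybrid_dn_width`).
#' @param sigma_d decision-noise SD on the decision variable (`bayes_dn`,
#'   `hybrid_dn_width`).
#' @param kappa_levels one criterion per eccentricity level
#'   (`nonparametric`).
#' @return an object of class `observer_params`.
#' @examples
#' observer_params("lin", sigma_x = c(0.35, 0.55, 1, 2), lapse = 0.03,
#'                 kappa0 = 0.4, kappa1 = 0.7)
#' @export
observer_params <- function(model, sigma_x,
                            levels = c(0, 4.8, 9.6, 16.8),
                            lapse = 0, sigma_y = 0.48,
                            p_common = NULL, kappa = NULL,
                            kappa0 = NULL, kappa1 = NULL,
                            history_weights = NULL,
                            assumed_intercept = NULL, assumed_slope = NULL,
                            sigma_y_assumed = NULL, sigma_d = NULL,
                            kappa_levels = NULL) {
  model <- match_model(model)
  if (!is.null(names(sigma_x))) {
    levels <- as.numeric(names(sigma_x))
    sigma_x <- unname(sigma_x)
  }
  levels <- as.numeric(levels)
  if (length(sigma_x) != length(levels)) {
    stop("`sigma_x` must supply one value per eccentricity level",
         call. = FALSE)
  }
  if (any(!is.finite(sigma_x)) || any(sigma_x <= 0)) {
    stop("all `sigma_x` must be strictly positive", call. = FALSE)
  }
  if (lapse < 0 || lapse > 1) stop("`lapse` must lie in [0, 1]", call. = FALSE)
  if (sigma_y < 0) stop("`sigma_y` must be nonnegative", call. = FALSE)

  need <- switch(model,
    fixed = "kappa",
    bayes = "p_common",
    lin = c("kappa0", "kappa1"),
    history = c("kappa0", "history_weights"),
    noise_mismatch = c("assumed_intercept", "assumed_slope"),
    width_mismatch = c("p_common", "sigma_y_assumed"),
    bayes_dn = c("p_common", "sigma_d"),
    hybrid_dn_width = c("p_common", "sigma_y_assumed", "sigma_d"),
    nonparametric = "kappa_levels",
    height = character(0))
  supplied <- c(p_common = !is.null(p_common), kappa = !is.null(kappa),
                kappa0 = !is.null(kappa0), kappa1 = !is.null(kappa1),
                history_weights = !is.null(history_weights),
                assumed_intercept = !is.null(assumed_intercept),
                assumed_slope = !is.null(assumed_slope),
                sigma_y_assumed = !is.null(sigma_y_assumed),
                sigma_d = !is.null(sigma_d),
                kappa_levels = !is.null(kappa_levels))
  missing <- setdiff(need, names(supplied)[supplied])
  if (length(missing)) {
    stop(sprintf("model '%s' requires parameter(s): %s", model,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(supplied)[supplied], need)
  if (length(extra)) {
    stop(sprintf("parameter(s) not used by model '%s': %s", model,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  if (model == "noise_mismatch") {
    p_common <- 0.5  # fixed by construction to keep the model identifiable
    sig_ass <- assumed_intercept + assumed_slope * sigma_x
    if (assumed_intercept < 0 || any(sig_ass <= 0)) {
      stop("assumed-noise mapping must yield positive SDs at every level",
           call. = FALSE)
    }
  }
  if (model == "history") {
    if (length(history_weights) != 5L) {
      stop("`history_weights` must have length 5 (lags 0..4)", call. = FALSE)
    }
  }
  if (model == "nonparametric" && length(kappa_levels) != length(levels)) {
    stop("`kappa_levels` must supply one criterion per level", call. = FALSE)
  }
  if (!is.null(sigma_d) && sigma_d <= 0) {
    stop("`sigma_d` must be positive", call. = FALSE)
  }
  if (!is.null(sigma_y_assumed) && sigma_y_assumed <= 0) {
    stop("`sigma_y_assumed` must be positive", call. = FALSE)
  }
  structure(list(
    model = model, levels = levels, sigma_x = as.numeric(sigma_x),
    lapse = as.numeric(lapse), sigma_y = as.numeric(sigma_y),
    p_common = p_common, kappa = kappa, kappa0 = kappa0, kappa1 = kappa1,
    history_weights = history_weights,
    assumed_intercept = assumed_intercept, assumed_slope = assumed_slope,
    sigma_y_assumed = sigma_y_assumed, sigma_d = sigma_d,
    kappa_levels = kappa_levels
  ), class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("Observer model '%s'\n", x$model))
  cat("  sigma_x (dva):",
      paste(sprintf("%s=%.3g", format(x$levels), x$sigma_x), collapse = ", "),
      "\n")
  cat(sprintf("  lapse = %.3g, sigma_y = %.3g\n", x$lapse, x$sigma_y))
  extras <- c("p_common", "kappa", "kappa0", "kappa1", "sigma_y_assumed",
              "sigma_d", "assumed_intercept", "assumed_slope")
  for (f in extras) {
    if (!is.null(x[[f]])) cat(sprintf("  %s = %.4g\n", f, x[[f]]))
  }
  if (!is.null(x$history_weights)) {
    cat("  history weights:", paste(format(x$history_weights), collapse = ", "),
        "\n")
  }
  if (!is.null(x$kappa_levels)) {
    cat("  per-level criteria:", paste(format(x$kappa_levels), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# noise SD per trial (by eccentricity level)
trial_sigma <- function(params, trials) {
  params$sigma_x[match_level(trials$eccentricity, params$levels)]
}
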