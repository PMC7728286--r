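# Plain-text file formats: trial tables, parameter files, posterior samples.
# All files are tab-delimited with a header row; comment lines start with '#'.

provenance_header <- function(kind, seed = NULL, extra = character(0)) {
  h <- c(sprintf("# collinobs %s", kind),
         sprintf("# written %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  if (!is.null(seed)) h <- c(h, sprintf("# seed %d", as.integer(seed)))
  c(h, extra)
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
}

#' Read and write trial tables
#'
#' Trial tables are tab-delimited text with columns `subject_id, session,
#' block, trial_index, task, eccentricity, y_left, y_right, category,
#' response`; a missing response is an empty field; comment lines start with
#' `#`. `read_trials()` validates the schema and labels and names the first
#' offending row in its error messages.
#'
#' @param trials a `cj_trials` data frame.
#' @param path file path.
#' @return `read_trials()` returns a `cj_trials` data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  write_tsv_with_header(as.data.frame(trials), path,
                        provenance_header("trial table",
                                          attr(trials, "rng_seed")))
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  head_lines <- readLines(path, n = 10L)
  seed_line <- grep("^# seed ", head_lines, value = TRUE)
  seed <- if (length(seed_line)) {
    as.integer(sub("^# seed ", "", seed_line[1]))
  } else NA_integer_
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   na.strings = "")
  missing_cols <- setdiff(trial_columns, names(df))
  if (length(missing_cols)) {
    stop("malformed trial table: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("session", "block", "trial_index")) {
    df[[col]] <- as.integer(df[[col]])
  }
  bad_task <- which(!df$task %in% c("collinearity", "height"))
  if (length(bad_task)) {
    stop(sprintf("malformed trial table: unknown task label '%s' in row %d",
                 df$task[bad_task[1]], bad_task[1]), call. = FALSE)
  }
  ok_cat <- ifelse(df$task == "collinearity",
                   df$category %in% c("collinear", "noncollinear"),
                   df$category %in% c("left_higher", "right_higher"))
  if (any(!ok_cat)) {
    i <- which(!ok_cat)[1]
    stop(sprintf("malformed trial table: category '%s' invalid for task '%s' in row %d",
                 df$category[i], df$task[i], i), call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  new_trials(df, seed = seed)
}

#' Read and write observer parameter files
#'
#' Parameter files are plain-text `key<TAB>value` pairs: `model`, the scalar
#' parameters by name, and the noise profile as `sigma_x_<level>` entries.
#'
#' @param params an [observer_params()].
#' @param path file path.
#' @return `read_observer_params()` returns an [observer_params()];
#'   `write_observer_params()` returns `path` invisibly.
#' @export
write_observer_params <- function(params, path) {
  stopifnot(inherits(params, "observer_params"))
  kv <- c(model = params$model,
          setNames(format(params$sigma_x, digits = 17),
                   paste0("sigma_x_", level_key(params$levels))),
          lapse = format(params$lapse, digits = 17),
          sigma_y = format(params$sigma_y, digits = 17))
  scalars <- c("p_common", "kappa", "kappa0", "kappa1", "assumed_intercept",
               "assumed_slope", "sigma_y_assumed", "sigma_d")
  if (params$model == "noise_mismatch") {
    scalars <- setdiff(scalars, "p_common")  # fixed at 0.5 by construction
  }
  for (f in scalars) {
    if (!is.null(params[[f]])) kv[f] <- format(params[[f]], digits = 17)
  }
  if (!is.null(params$history_weights)) {
    kv[paste0("w", 0:4)] <- format(params$history_weights, digits = 17)
  }
  if (!is.null(params$kappa_levels)) {
    kv[paste0("kappa_", level_key(params$levels))] <-
      format(params$kappa_levels, digits = 17)
  }
  writeLines(c(provenance_header("observer parameters"),
               paste(names(kv), unname(kv), sep = "\t")), path)
  invisible(path)
}

#' @rdname write_observer_params
#' @export
read_observer_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("malformed parameter file: expected key<TAB>value lines",
         call. = FALSE)
  }
  kv <- setNames(vapply(parts, `[[`, "", 2L), vapply(parts, `[[`, "", 1L))
  model <- match_model(kv[["model"]])
  sig_keys <- grep("^sigma_x_", names(kv), value = TRUE)
  levels <- as.numeric(sub("^sigma_x_", "", sig_keys))
  ord <- order(levels)
  num <- function(key) if (key %in% names(kv)) as.numeric(kv[[key]]) else NULL
  args <- list(model = model,
               sigma_x = as.numeric(kv[sig_keys])[ord],
               levels = levels[ord],
               lapse = num("lapse"), sigma_y = num("sigma_y"),
               p_common = num("p_common"), kappa = num("kappa"),
               kappa0 = num("kappa0"), kappa1 = num("kappa1"),
               assumed_intercept = num("assumed_intercept"),
               assumed_slope = num("assumed_slope"),
               sigma_y_assumed = num("sigma_y_assumed"),
               sigma_d = num("sigma_d"))
  if (all(paste0("w", 0:4) %in% names(kv))) {
    args$history_weights <- as.numeric(kv[paste0("w", 0:4)])
  }
  kl <- paste0("kappa_", level_key(levels[ord]))
  if (all(kl %in% names(kv))) args$kappa_levels <- as.numeric(kv[kl])
  do.call(observer_params, args[!vapply(args, is.null, logical(1))])
}

#' Read and write posterior sample files
#'
#' `write_posterior()` stores the merged draws as a tab-delimited table with
#' a metadata header (model, seed, chain layout, R-hat), and the pointwise
#' log-likelihood matrix alongside it in `<path>.pointwise`.
#' `read_posterior()` restores a reduced `cj_posterior` sufficient for
#' [psis_loo()] and [posterior_predictive_curves()].
#'
#' @param post a `cj_posterior`.
#' @param path file path for the draws table.
#' @return `read_posterior()` returns a `cj_posterior`; `write_posterior()`
#'   returns `path` invisibly.
#' @export
write_posterior <- function(post, path) {
  stopifnot(inherits(post, "cj_posterior"))
  extra <- c(sprintf("# model %s", post$model),
             sprintf("# chains %d samples %d burn_in %d", post$n_chains,
                     post$n_samples, post$burn_in),
             sprintf("# rhat %s", paste(format(post$rhat, digits = 6),
                                        collapse = " ")),
             sprintf("# sigma_y %s", format(attr(post$prior, "sigma_y"),
                                            digits = 17)))
  con_noise <- attr(post$prior, "constrained_noise")
  if (!is.null(con_noise)) {
    extra <- c(extra, sprintf("# constrained_noise %s",
                              paste(names(con_noise), format(con_noise,
                                                             digits = 17),
                                    sep = "=", collapse = " ")))
  }
  df <- as.data.frame(post$draws)
  df$log_lik <- post$log_lik
  write_tsv_with_header(df, path, provenance_header("posterior draws",
                                                    post$seed, extra))
  pw <- as.data.frame(post$pointwise)
  names(pw) <- paste0("trial_", seq_len(ncol(pw)))
  write_tsv_with_header(pw, paste0(path, ".pointwise"),
                        provenance_header("pointwise log-likelihood",
                                          post$seed))
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  lines <- readLines(path, n = 50L)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    ln <- grep(paste0("^# ", key, " "), meta, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^# ", key, " "), "", ln[1])
  }
  model <- get_meta("model")
  seed <- as.integer(get_meta("seed"))
  cfg <- as.integer(strsplit(get_meta("chains"), " ")[[1]][c(1, 3, 5)])
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  draws <- as.matrix(df[setdiff(names(df), "log_lik")])
  pw_path <- paste0(path, ".pointwise")
  pointwise <- if (file.exists(pw_path)) {
    as.matrix(read.delim(pw_path, comment.char = "#"))
  } else NULL
  sigma_y <- as.numeric(get_meta("sigma_y"))
  con <- get_meta("constrained_noise")
  con_noise <- NULL
  if (!is.null(con)) {
    kvs <- strsplit(strsplit(con, " ")[[1]], "=")
    con_noise <- setNames(as.numeric(vapply(kvs, `[[`, "", 2L)),
                          vapply(kvs, `[[`, "", 1L))
  }
  design_levels <- as.numeric(sub("^sigma_", "",
                                  grep("^sigma_[0-9]", colnames(draws),
                                       value = TRUE)))
  if (!length(design_levels) && !is.null(con_noise)) {
    design_levels <- as.numeric(names(con_noise))
  }
  design <- if (length(design_levels)) {
    collinearity_design(eccentricity_levels = sort(design_levels),
                        offset_sd = if (is.null(sigma_y) ||
                                        is.na(sigma_y)) 0.48 else sigma_y)
  } else {
    make_default_design()
  }
  prior <- prior_spec(model, design, constrained_noise = con_noise)
  rh <- get_meta("rhat")
  rhat <- if (is.null(rh)) NULL else {
    setNames(as.numeric(strsplit(rh, " +")[[1]]), prior$name)
  }
  structure(list(
    model = model, draws = draws, chain_draws = NULL,
    log_lik = df$log_lik, pointwise = pointwise, rhat = rhat,
    n_chains = cfg[1], n_samples = cfg[2], burn_in = cfg[3], seed = seed,
    prior = prior, map = NULL,
    n_trials = if (is.null(pointwise)) NA_integer_ else ncol(pointwise)
  ), class = "cj_posterior")
}
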