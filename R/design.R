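#' Task design: stimulus statistics and session structure
#'
#' A `cj_design` bundles the experiment's stimulus statistics: the possible
#' retinal eccentricity levels (vertical base positions, in degrees of visual
#' angle, dva), the standard deviation \eqn{\sigma_y} of a segment's vertical
#' position about its base, the prior probability that a trial is collinear,
#' and the block/session structure of the two tasks.
#'
#' On a collinear trial the left segment's vertical position is drawn from
#' \eqn{N(y, \sigma_y^2)} around the base eccentricity \eqn{y} and the right
#' segment is set equal to it; on a non-collinear trial (and on every height
#' judgment trial) the two positions are independent draws from the same
#' Gaussian.
#'
#' @param eccentricity_levels strictly increasing, nonnegative base positions
#'   (dva).
#' @param offset_sd SD \eqn{\sigma_y} of the vertical position about the base
#'   (dva). Must be nonnegative; 0 is a degenerate design accepted only by the
#'   collinearity-task generator.
#' @param prior_collinear probability that a trial is collinear, in (0, 1).
#' @param collinearity_block_size,height_block_size trials per block.
#' @param collinearity_blocks_per_session,height_blocks_per_session blocks of
#'   each task per session.
#' @param sessions number of sessions.
#' @return an object of class `cj_design`.
#' @examples
#' d <- collinearity_design()
#' d$offset_sd  # 0.48 dva
#' @export
collinearity_design <- function(eccentricity_levels = c(0, 4.8, 9.6, 16.8),
                                offset_sd = 0.48,
                                prior_collinear = 0.5,
                                collinearity_block_size = 200L,
                                height_block_size = 60L,
                                collinearity_blocks_per_session = 3L,
                                height_blocks_per_session = 2L,
                                sessions = 4L) {
  if (!is.numeric(eccentricity_levels) || length(eccentricity_levels) < 1L ||
      any(!is.finite(eccentricity_levels)) || any(eccentricity_levels < 0) ||
      is.unsorted(eccentricity_levels, strictly = TRUE)) {
    stop("`eccentricity_levels` must be strictly increasing and nonnegative",
         call. = FALSE)
  }
  if (!is.numeric(offset_sd) || length(offset_sd) != 1L ||
      !is.finite(offset_sd) || offset_sd < 0) {
    stop("`offset_sd` must be a single nonnegative number", call. = FALSE)
  }
  if (!is.numeric(prior_collinear) || length(prior_collinear) != 1L ||
      prior_collinear <= 0 || prior_collinear >= 1) {
    stop("`prior_collinear` must lie in (0, 1)", call. = FALSE)
  }
  design <- list(
    eccentricity_levels = as.numeric(eccentricity_levels),
    offset_sd = as.numeric(offset_sd),
    prior_collinear = as.numeric(prior_collinear),
    collinearity_block_size = assert_count(collinearity_block_size,
                                           "collinearity_block_size"),
    height_block_size = assert_count(height_block_size, "height_block_size"),
    collinearity_blocks_per_session =
      assert_count(collinearity_blocks_per_session,
                   "collinearity_blocks_per_session"),
    height_blocks_per_session = assert_count(height_blocks_per_session,
                                             "height_blocks_per_session"),
    sessions = assert_count(sessions, "sessions")
  )
  class(design) <- "cj_design"
  design
}

#' Default task design
#'
#' The experiment's stated conditions: eccentricity levels 0, 4.8, 9.6 and
#' 16.8 dva; offset SD 0.48 dva; 50/50 collinear/non-collinear mix; 200-trial
#' collinearity blocks and 60-trial height blocks; three collinearity and two
#' height blocks per session; four sessions.
#'
#' @return a `cj_design`.
#' @export
make_default_design <- function() {
  collinearity_design()
}

#' @export
print.cj_design <- function(x, ...) {
  cat("Collinearity/height task design\n")
  cat("  eccentricity levels (dva):",
      paste(format(x$eccentricity_levels), collapse = ", "), "\n")
  cat(sprintf("  offset SD sigma_y: %g dva, p(collinear) = %g\n",
              x$offset_sd, x$prior_collinear))
  cat(sprintf("  %d sessions; per session %d x %d-trial collinearity blocks, %d x %d-trial height blocks\n",
              x$sessions, x$collinearity_blocks_per_session,
              x$collinearity_block_size, x$height_blocks_per_session,
              x$height_block_size))
  invisible(x)
}

trial_columns <- c("subject_id", "session", "block", "trial_index", "task",
                   "eccentricity", "y_left", "y_right", "category", "response")

new_trials <- function(df, seed = NA_integer_) {
  df <- df[trial_columns]
  attr(df, "rng_seed") <- seed
  class(df) <- c("cj_trials", "data.frame")
  df
}

# session/block/trial bookkeeping for n trials of one task
task_structure <- function(n, block_size, blocks_per_session) {
  session_size <- block_size * blocks_per_session
  pos <- seq_len(n) - 1L
  data.frame(
    session = pos %/% session_size + 1L,
    block = (pos %% session_size) %/% block_size + 1L,
    trial_index = pos %% block_size + 1L
  )
}

#' Generate collinearity judgment trials
#'
#' Categories are exactly balanced: `round(prior_collinear * n_trials)` trials
#' are collinear, allocated as evenly as possible across sessions and shuffled
#' within session. Eccentricity levels are assigned uniformly at random per
#' trial. Collinear trials share one vertical position drawn from
#' \eqn{N(y, \sigma_y^2)}; non-collinear trials get two independent draws.
#'
#' @param design a [collinearity_design()].
#' @param n_trials number of trials (>= 1).
#' @param seed integer RNG seed; all randomness flows from it.
#' @param subject_id label recorded on each trial.
#' @return a `cj_trials` data frame with empty responses.
#' @examples
#' tr <- generate_collinearity_trials(make_default_design(), 600, seed = 1)
#' table(tr$category)  # exactly 300/300
#' @export
generate_collinearity_trials <- function(design, n_trials, seed,
                                         subject_id = "sim") {
  stopifnot(inherits(design, "cj_design"))
  n <- assert_count(n_trials, "n_trials")
  with_seed(seed, {
    n_coll <- round(design$prior_collinear * n)
    struct <- task_structure(n, design$collinearity_block_size,
                             design$collinearity_blocks_per_session)
    # allocate the collinear count across sessions by rounded cumulative share
    sess_sizes <- as.integer(table(struct$session))
    cum <- round(cumsum(sess_sizes) * (n_coll / n))
    cum[length(cum)] <- n_coll
    alloc <- diff(c(0L, cum))
    category <- unlist(lapply(seq_along(sess_sizes), function(s) {
      v <- c(rep("collinear", alloc[s]),
             rep("noncollinear", sess_sizes[s] - alloc[s]))
      sample(v)
    }), use.names = FALSE)
    lv <- design$eccentricity_levels
    ecc <- lv[sample.int(length(lv), n, replace = TRUE)]
    y_left <- rnorm(n, ecc, design$offset_sd)
    y_right <- rnorm(n, ecc, design$offset_sd)
    coll <- category == "collinear"
    y_right[coll] <- y_left[coll]
    new_trials(data.frame(
      subject_id = subject_id, session = struct$session, block = struct$block,
      trial_index = struct$trial_index, task = "collinearity",
      eccentricity = ecc, y_left = y_left, y_right = y_right,
      category = category, response = NA_character_,
      stringsAsFactors = FALSE
    ), seed = as.integer(seed))
  })
}

#' Generate height judgment trials
#'
#' Both segment positions are independent draws from \eqn{N(y, \sigma_y^2)},
#' exactly as in the non-collinear condition of the collinearity task. The
#' category is `right_higher` iff `y_right > y_left`. A degenerate design with
#' `offset_sd == 0` is rejected (ties are undefined); exact floating-point
#' ties are re-drawn.
#'
#' @inheritParams generate_collinearity_trials
#' @return a `cj_trials` data frame with empty responses.
#' @export
generate_height_trials <- function(design, n_trials, seed,
                                   subject_id = "sim") {
  stopifnot(inherits(design, "cj_design"))
  if (design$offset_sd <= 0) {
    stop("height judgment trials require `offset_sd` > 0 (ties undefined)",
         call. = FALSE)
  }
  n <- assert_count(n_trials, "n_trials")
  with_seed(seed, {
    struct <- task_structure(n, design$height_block_size,
                             design$height_blocks_per_session)
    lv <- design$eccentricity_levels
    ecc <- lv[sample.int(length(lv), n, replace = TRUE)]
    y_left <- rnorm(n, ecc, design$offset_sd)
    y_right <- rnorm(n, ecc, design$offset_sd)
    while (any(tie <- y_left == y_right)) {
      y_right[tie] <- rnorm(sum(tie), ecc[tie], design$offset_sd)
    }
    new_trials(data.frame(
      subject_id = subject_id, session = struct$session, block = struct$block,
      trial_index = struct$trial_index, task = "height",
      eccentricity = ecc, y_left = y_left, y_right = y_right,
      category = ifelse(y_right > y_left, "right_higher", "left_higher"),
      response = NA_character_,
      stringsAsFactors = FALSE
    ), seed = as.integer(seed))
  })
}

response_labels <- function(task) {
  if (task == "collinearity") c("collinear", "noncollinear")
  else c("left_higher", "right_higher")
}

validate_trials <- function(trials, task = NULL, need_response = FALSE) {
  if (!is.data.frame(trials) || !all(trial_columns %in% names(trials))) {
    stop("trial table must contain columns: ",
         paste(trial_columns, collapse = ", "), call. = FALSE)
  }
  if (!is.null(task) && !all(trials$task == task)) {
    stop(sprintf("expected %s-task trials only", task), call. = FALSE)
  }
  if (need_response && anyNA(trials$response)) {
    stop("trials must carry responses", call. = FALSE)
  }
  invisible(trials)
}
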