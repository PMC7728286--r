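# internal helpers shared across modules

# evaluate `code` with the RNG seeded to `seed`, restoring global RNG state
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a stream of child seeds from one master seed (kept < 2^31)
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

# canonical (unpadded) text key for each eccentricity level
level_key <- function(levels) {
  vapply(levels, function(l) format(l), character(1))
}

# match eccentricities against design levels, with numeric tolerance
match_level <- function(ecc, levels, tol = 1e-8) {
  idx <- match(ecc, levels)  # fast exact path
  if (anyNA(idx)) {
    miss <- which(is.na(idx))
    for (u in unique(ecc[miss])) {
      j <- which(abs(levels - u) < tol)
      if (length(j) == 1L) idx[miss][ecc[miss] == u] <- j
    }
  }
  if (anyNA(idx)) {
    bad <- unique(ecc[is.na(idx)])
    stop("eccentricity level(s) not covered by the noise profile/design: ",
         paste(format(bad), collapse = ", "), call. = FALSE)
  }
  idx
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch), cached per order
.quad_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.quad_cache[[key]])) return(.quad_cache[[key]])
  n <- assert_count(n, "n", min = 2L)
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  res <- list(x = e$values[ord], w = 2 * e$vectors[1, ord]^2)
  .quad_cache[[key]] <- res
  res
}
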