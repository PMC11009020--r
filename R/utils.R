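# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded generators do not perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a user seed; kept below 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 9973) %% 2147483647
}

stop_bad_arg <- function(...) stop(..., call. = FALSE)

# Column variances of a numeric matrix, denominator n - 1.
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(stats::setNames(rep(0, ncol(x)), colnames(x)))
  mu <- colMeans(x)
  (colMeans(x * x) - mu * mu) * n / (n - 1)
}

# Pearson correlations of each column of x with y; zero-variance columns -> 0.
cor_with <- function(x, y) {
  sx <- sqrt(col_vars(x))
  r <- suppressWarnings(as.vector(stats::cor(x, y)))
  r[!is.finite(r) | sx == 0] <- 0
  stats::setNames(r, colnames(x))
}
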