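# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible seed substream
#'
#' Deterministically maps a base seed and a character tag to a new 32-bit
#' seed, so that independent stages (cohorts, subjects, per-k restarts) each
#' get their own stream while the whole study is driven by one seed.
#'
#' @param seed Integer base seed.
#' @param tag Character label of the substream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' seed_substream(1, "cohort:645")
seed_substream <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.double(seed) %% m
  for (ch in utf8ToInt(tag)) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Scalar validation helpers ---------------------------------------------------

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop_param("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_scalar <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_param("`%s` must be a single finite number", name)
  low_ok <- if (strict_min) x > min else x >= min
  high_ok <- if (strict_max) x < max else x <= max
  if (!low_ok || !high_ok)
    stop_param("`%s` = %g is outside the allowed range", name, x)
  as.double(x)
}

# Symmetry check used by several modules; returns the maximum absolute
# asymmetry of a square matrix.
max_asymmetry <- function(m) {
  max(abs(m - t(m)))
}
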