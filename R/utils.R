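#' @keywords internal
"_PACKAGE"

# Derive a 32-bit sub-seed for a named random stream from a master seed.
# Keeps every pipeline stage reproducible on its own: re-running one stage
# with the same master seed draws the same numbers regardless of what ran
# before it.
stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

# Evaluate `expr` under a named stream of the master seed, restoring the
# caller's RNG state afterwards.
with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  expr
}

# Stratified k-fold assignment; returns an integer vector of fold ids in
# 1..k, deterministic given the RNG state. `strata` may be NULL for plain
# random folds.
make_folds <- function(n, k, strata = NULL) {
  if (k < 2L) stop("at least 2 folds are required")
  if (n < k) stop("cannot split ", n, " samples into ", k, " folds")
  fold <- integer(n)
  if (is.null(strata)) strata <- rep(1L, n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop("invalid configuration field '", field, "': ", msg, call. = FALSE)
}
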