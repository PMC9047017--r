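# internal helpers shared across modules

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lo), format(hi)), call. = FALSE)
  x
}

# Symmetric matrix check with informative failure.
check_square_symmetric <- function(m, name, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop(sprintf("'%s' is not symmetric (max asymmetry %.3g)",
                 name, max(abs(m - t(m)))), call. = FALSE)
  invisible(m)
}

default_region_labels <- function(n) sprintf("R%03d", seq_len(n))

match_labels <- function(labels, region, what = "region") {
  idx <- match(region, labels)
  if (anyNA(idx))
    stop(sprintf("unknown %s: %s", what,
                 paste(region[is.na(idx)], collapse = ", ")), call. = FALSE)
  idx
}
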