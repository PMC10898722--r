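# Internal helpers: seeded evaluation, child-seed derivation, pseudo-inverse.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic operations in the package go
# through this so that identical seeds give byte-identical results regardless
# of what the caller's session has done before.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seed from a master seed and an index path, e.g.
# child_seed(7, participant = 3, rep = 2, fold = 1). Stays below 2^31.
child_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# Moore-Penrose pseudo-inverse via SVD with a relative tolerance.
pinv <- function(x, tol = 1e-10) {
  s <- svd(x)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(x), nrow(x)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

stop_invalid <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
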