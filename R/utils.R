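# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Row-wise Euclidean norms of a matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < .Machine$double.eps) stop("cannot normalize a zero-length vector")
  v / n
}

# Pairwise Euclidean distances between rows of `a` (n x 3) and rows of
# `b` (m x 3), returned as an n x m matrix.
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a * a), rowSums(b * b), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# A deterministic unit vector perpendicular to `axis`.
perp_vector <- function(axis) {
  axis <- unit(axis)
  e <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(e - sum(e * axis) * axis)
}

# Wrap an angle into [0, 2*pi).
wrap_angle <- function(theta) theta %% (2 * pi)

`%||%` <- function(a, b) if (is.null(a)) b else a
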