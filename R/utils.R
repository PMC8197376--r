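# Internal helpers: seeded RNG scoping, seed derivation, matrix resizing.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's session RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed from a parent seed plus arbitrary string/integer
# tags; result always in [1, 2^31 - 2].
derive_seed <- function(seed, ...) {
  tags <- list(...)
  h <- as.double(seed) %% 2147483647
  for (t in tags) {
    if (is.character(t)) t <- sum(utf8ToInt(t) * seq_along(utf8ToInt(t)))
    h <- (h * 69069 + as.double(t) * 40503 + 12345) %% 2147483647
  }
  as.integer(h) + 1L
}

# Area-average resize of a numeric matrix to nr x nc (used to shrink mel
# spectrograms before feeding the network). Each output cell averages the
# exact input interval it covers, so downscaling is anti-aliased: narrow
# spectral ridges are pooled, never skipped.
resize_matrix <- function(m, nr, nc) {
  stopifnot(is.matrix(m), nr >= 1, nc >= 1)
  area_weights <- function(n_from, n_to) {
    # n_to x n_from averaging operator; row i covers input span
    # [(i-1) * r, i * r), r = n_from / n_to
    r <- n_from / n_to
    W <- matrix(0, n_to, n_from)
    for (i in seq_len(n_to)) {
      s <- (i - 1) * r; e <- i * r
      j <- seq.int(floor(s) + 1L, min(n_from, ceiling(e)))
      W[i, j] <- (pmin(e, j) - pmax(s, j - 1)) / r
    }
    W
  }
  A <- area_weights(nrow(m), nr)
  B <- area_weights(ncol(m), nc)
  A %*% m %*% t(B)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
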