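# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so package functions never clobber the global stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive per-item child seeds from one parent seed; kept below 2^31.
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

# Squared Euclidean cross-distances between rows of A (n x d) and B (m x d).
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Nearest row of B for each row of A; ties go to the lowest index.
nearest_index <- function(A, B) {
  max.col(-cross_dist2(A, B), ties.method = "first")
}
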