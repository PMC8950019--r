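# Seed plumbing shared by the generator, CNN training and the pipeline.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministically derive a per-stage seed from a master seed and a tag,
# staying inside the positive 32-bit integer range.
derive_seed <- function(master, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483647)
}

frob <- function(A) sqrt(sum(A^2))

is_square <- function(A) is.matrix(A) && nrow(A) == ncol(A)

# Symmetric matrix power via eigendecomposition with a relative eigenvalue
# floor; used for inverse square roots of covariance references.
sym_power <- function(A, p, floor_rel = 0) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  vals <- e$values
  if (floor_rel > 0) vals <- pmax(vals, floor_rel * max(vals))
  if (any(vals <= 0) && p < 0)
    stop("matrix is numerically singular; supply more data or raise the eigenvalue floor")
  e$vectors %*% (vals^p * t(e$vectors))
}
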