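# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage seed fan-out from a single root seed.
# Must stay below .Machine$integer.max (R seeds are 32-bit).
.derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (abs(seed) * 1009L + h * 31L) %% 2147483647L
}

.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# genes x cells matrix from either a plain/sparse matrix or a scaled_matrix
.values <- function(x) {
  if (inherits(x, "scaled_matrix")) x$values else x
}

# coerce to general column-sparse form (dgCMatrix) regardless of input class
.as_dgc <- function(x) {
  methods::as(methods::as(methods::as(Matrix::Matrix(x), "generalMatrix"),
                          "CsparseMatrix"), "dMatrix")
}
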