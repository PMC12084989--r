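# Internal helpers shared across modules.

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
  expr
}

# Numerically stable binary cross-entropy with logits:
# -[y*log(sigmoid(z)) + (1-y)*log(1-sigmoid(z))]
bce_with_logits <- function(z, y) {
  pmax(z, 0) - z * y + log1p(exp(-abs(z)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_num_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop(sprintf("'%s' contains missing values", arg))
  x
}

check_labels <- function(y, J) {
  if (anyNA(y)) stop("labels contain missing values")
  if (any(y != floor(y))) {
    bad <- which(y != floor(y))[1L]
    stop(sprintf("non-integer label %g at row %d", y[bad], bad))
  }
  y <- as.integer(y)
  bad <- which(y < 0L | y >= J)
  if (length(bad))
    stop(sprintf("label out of range {0,...,%d}: value %d at row %d",
                 J - 1L, y[bad[1L]], bad[1L]))
  y
}
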