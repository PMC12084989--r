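#' Binary deep neural network health-space models
#'
#' Fits one of the four binary DNN variants obtained from a 4-level ordinal
#' outcome. `"zero_vs_three"` keeps only the extreme categories (rows with
#' labels 1 or 2 are discarded) and models
#' \eqn{\log \Pr(Y = 3)/\Pr(Y = 0) = \alpha + W^\top\beta}. The three
#' collapsed variants relabel every row to the threshold indicator
#' \eqn{I(Y > j)} for j = 0 (`"zero_vs_rest"`), j = 1 (`"low_vs_high"`),
#' j = 2 (`"rest_vs_three"`), then fit the binary model on all rows. The
#' optimizer and hyperparameters are identical to [donn()]'s — with J = 2
#' the ordinal loss is exactly the binary cross-entropy — so differences in
#' health-space quality are attributable to how the ordinal information is
#' used, not to tuning.
#'
#' @param x covariate matrix.
#' @param y ordinal labels in `{0, ..., J-1}`.
#' @param mode one of `"zero_vs_three"`, `"zero_vs_rest"`, `"low_vs_high"`,
#'   `"rest_vs_three"`.
#' @param J number of categories of the original outcome (default 4).
#' @param ... passed to [donn()] (`hidden`, `learning_rate`, `batch_size`,
#'   `epochs`, `patience`, `validation_fraction`, `seed`, ...).
#' @return an object of class `c("binary_dnn", "donn")` with `J = 2`; the
#'   collapse `mode` and number of retained rows are recorded.
#' @export
binary_dnn <- function(x, y,
                       mode = c("zero_vs_three", "zero_vs_rest",
                                "low_vs_high", "rest_vs_three"),
                       J = 4L, ...) {
  mode <- match.arg(mode)
  x <- as_num_matrix(x)
  J <- as.integer(J)
  y <- check_labels(y, J)
  cl <- collapse_labels(y, mode, J)
  x2 <- x[cl$keep, , drop = FALSE]
  y2 <- cl$y
  if (length(unique(y2)) < 2L)
    stop(sprintf("collapse mode '%s' leaves a single class", mode))
  fit <- donn(x2, y2, J = 2L, ...)
  fit$mode <- mode
  fit$n_used <- length(y2)
  fit$call <- match.call()
  class(fit) <- c("binary_dnn", "donn")
  fit
}

# Map an ordinal response to a binary one. zero_vs_three keeps only the
# extreme categories; the collapsed modes relabel every row to I(y > j).
collapse_labels <- function(y, mode, J) {
  if (mode == "zero_vs_three") {
    keep <- y == 0L | y == J - 1L
    list(keep = which(keep), y = as.integer(y[keep] == J - 1L))
  } else {
    thr <- switch(mode, zero_vs_rest = 0L, low_vs_high = 1L,
                  rest_vs_three = J - 2L)
    list(keep = seq_along(y), y = as.integer(y > thr))
  }
}

#' @export
print.binary_dnn <- function(x, ...) {
  lab <- c(zero_vs_three = "0 vs 3 (middle categories discarded)",
           zero_vs_rest = "0 vs 1+2+3", low_vs_high = "0+1 vs 2+3",
           rest_vs_three = "0+1+2 vs 3")[x$mode]
  cat(sprintf("Binary DNN health-space model: %s, n used = %d\n",
              lab, x$n_used))
  NextMethod()
}
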