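#' Proportional odds model baseline
#'
#' Maximum-likelihood cumulative-logit regression with shared slopes,
#' \deqn{\log \frac{\Pr(Y > j \mid x)}{\Pr(Y \le j \mid x)} =
#'   \alpha_j + x^\top\beta,}
#' the classical statistical health-space model against which the network
#' models are compared. Fitting is delegated to [MASS::polr()]; its
#' `logit P(Y <= j) = zeta_j - eta` parameterization is remapped to the
#' `Y > j` form used throughout this package (`alpha_j = -zeta_j`, `beta`
#' unchanged), so the health score is `x %*% beta` on the original covariate
#' scale.
#'
#' @param x covariate matrix (full column rank).
#' @param y integer labels in `{0, ..., J-1}`; all categories present.
#' @param J number of ordered categories; defaults to `max(y) + 1`.
#' @return an object of class `pom` with `alpha` (strictly decreasing),
#'   `beta`, `J`, `p`, `logLik`, and convergence information.
#' @seealso [donn()], [health_score()]
#' @export
pom <- function(x, y, J = NULL) {
  x <- as_num_matrix(x)
  if (is.null(J)) J <- max(y) + 1L
  J <- as.integer(J)
  y <- check_labels(y, J)
  if (length(setdiff(0:(J - 1L), unique(y))))
    stop("all J categories must be present to fit the proportional odds model")
  df <- as.data.frame(x)
  names(df) <- paste0("x", seq_len(ncol(x)))
  df$.y <- factor(y, levels = 0:(J - 1L))
  fit <- tryCatch(
    MASS::polr(.y ~ ., data = df, method = "logistic", Hess = FALSE),
    error = function(e)
      stop("proportional odds fit failed (possible separation): ",
           conditionMessage(e)))
  if (!is.null(fit$convergence) && fit$convergence != 0)
    stop("proportional odds optimizer did not converge (code ",
         fit$convergence, ")")
  beta <- unname(stats::coef(fit))
  alpha <- -unname(fit$zeta)          # Y > j parameterization
  structure(list(alpha = alpha, beta = beta, J = J, p = ncol(x),
                 logLik = as.numeric(stats::logLik(fit)),
                 deviance = fit$deviance, n = length(y),
                 call = match.call()),
            class = "pom")
}

#' @export
coef.pom <- function(object, ...) {
  list(alpha = object$alpha, beta = object$beta)
}

#' @export
logLik.pom <- function(object, ...) {
  structure(object$logLik, df = length(object$beta) + length(object$alpha),
            class = "logLik")
}

#' @rdname health_score
#' @export
health_score.pom <- function(object, x, ...) {
  x <- as_num_matrix(x)
  if (ncol(x) != object$p)
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(x), object$p))
  drop(x %*% object$beta)
}

#' @export
predict.pom <- function(object, newdata,
                        type = c("cumulative", "prob", "class", "score"),
                        ...) {
  type <- match.arg(type)
  s <- health_score(object, newdata)
  if (type == "score") return(s)
  cum <- stats::plogis(outer(s, object$alpha, "+"))
  colnames(cum) <- paste0("gt", 0:(object$J - 2L))
  if (type == "cumulative") return(cum)
  probs <- cbind(1, cum) - cbind(cum, 0)
  colnames(probs) <- paste0("cat", 0:(object$J - 1L))
  if (type == "prob") return(probs)
  as.integer(max.col(probs) - 1L)
}

#' @export
print.pom <- function(x, ...) {
  cat(sprintf("Proportional odds model (J = %d, p = %d, n = %d)\n",
              x$J, x$p, x$n))
  cat(sprintf("  alpha: %s\n",
              paste(format(round(x$alpha, 3)), collapse = ", ")))
  cat(sprintf("  beta:  %s\n",
              paste(format(round(x$beta, 3)), collapse = ", ")))
  cat(sprintf("  log-likelihood: %.2f\n", x$logLik))
  invisible(x)
}
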