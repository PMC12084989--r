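#' Expand ordinal labels into threshold indicators
#'
#' Encodes an ordinal response `y` in `{0, ..., J-1}` as the n x (J-1)
#' binary matrix with entry (i, j) = I(y_i > j), j = 0, ..., J-2 — the
#' targets of the J-1 cumulative binary classifiers that define the ordinal
#' network's loss.
#'
#' @param y integer labels in `{0, ..., J-1}`.
#' @param J number of ordered categories.
#' @return integer matrix with `J - 1` columns named `gt0`, `gt1`, ...
#' @examples
#' encode_levels(c(0, 1, 2, 3), 4)
#' @export
encode_levels <- function(y, J) {
  J <- as.integer(J)
  if (J < 2L) stop("J must be >= 2")
  y <- check_labels(y, J)
  enc <- 1L * outer(y, 0:(J - 2L), ">")
  colnames(enc) <- paste0("gt", 0:(J - 2L))
  enc
}

#' Ordinal cross-entropy loss
#'
#' The training loss of the deep ordinal network: the sum over samples and
#' thresholds of the binary cross-entropies of the J-1 cumulative
#' classifiers,
#' \deqn{-\sum_i \sum_j \{ y_i^{(j)} \log \sigma(s_i + \alpha_j) +
#'  (1 - y_i^{(j)}) \log(1 - \sigma(s_i + \alpha_j)) \},}
#' with \eqn{s_i} the shared score of sample i, \eqn{\alpha_j} the threshold
#' intercepts and \eqn{y^{(j)} = I(y > j)}. Computed in log-sum-exp form so
#' it is finite for logits far into either tail.
#'
#' @param scores length-n vector of shared linear scores \eqn{W_i^\top\beta}.
#' @param alpha length J-1 vector of threshold intercepts.
#' @param y integer labels in `{0, ..., J-1}` with `J = length(alpha) + 1`.
#' @return a single non-negative number.
#' @examples
#' donn_loss(0, c(0, 0, 0), 2) # 3 * log(2)
#' @export
donn_loss <- function(scores, alpha, y) {
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (!all(is.finite(alpha))) stop("alpha must be finite")
  J <- length(alpha) + 1L
  enc <- encode_levels(y, J)
  z <- outer(as.numeric(scores), as.numeric(alpha), "+")
  loss <- sum(bce_with_logits(z, enc))
  if (!is.finite(loss)) stop("loss is not finite")
  loss
}

## ---- network internals -----------------------------------------------------
## The feature map f is a stack of dense ReLU layers; W = f(X) is the last
## hidden activation (or X itself with zero hidden layers), and the model is
## logit Pr(Y > j | x) = alpha_j + f(x)' beta.

nn_shapes <- function(p, hidden) {
  dims <- c(p, hidden)
  lapply(seq_along(hidden), function(l) c(dims[l], dims[l + 1L]))
}

nn_init <- function(p, hidden, J) {
  # He initialization for ReLU layers; small-variance output coefficients
  shapes <- nn_shapes(p, hidden)
  q <- if (length(hidden)) hidden[length(hidden)] else p
  params <- list(
    W = lapply(shapes, function(s)
      matrix(stats::rnorm(prod(s), sd = sqrt(2 / s[1L])), s[1L], s[2L])),
    b = lapply(shapes, function(s) numeric(s[2L])),
    beta = stats::rnorm(q, sd = sqrt(1 / q)),
    alpha = seq(0.5, -0.5, length.out = J - 1L)
  )
  params
}

nn_forward <- function(params, X, keep = FALSE) {
  acts <- list(X)
  A <- X
  for (l in seq_along(params$W)) {
    A <- sweep(A %*% params$W[[l]], 2L, params$b[[l]], "+")
    A <- pmax(A, 0)
    if (keep) acts[[l + 1L]] <- A
  }
  s <- drop(A %*% params$beta)
  if (keep) list(score = s, final = A, acts = acts) else s
}

# Gradient of the summed ordinal BCE loss, divided by n (mean form for the
# optimizer). Returns a list with the same structure as params.
nn_grad <- function(params, X, enc) {
  n <- nrow(X)
  fw <- nn_forward(params, X, keep = TRUE)
  z <- outer(fw$score, params$alpha, "+")
  E <- stats::plogis(z) - enc                      # d loss / d z
  g_alpha <- colSums(E) / n
  ds <- rowSums(E) / n                             # d loss / d score
  g_beta <- drop(crossprod(fw$final, ds))
  gW <- vector("list", length(params$W))
  gb <- vector("list", length(params$W))
  dA <- tcrossprod(ds, params$beta)                # n x q
  for (l in rev(seq_along(params$W))) {
    dZ <- dA * (fw$acts[[l + 1L]] > 0)             # ReLU mask
    gW[[l]] <- crossprod(fw$acts[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1L) dA <- tcrossprod(dZ, params$W[[l]])
  }
  list(W = gW, b = gb, beta = g_beta, alpha = g_alpha)
}

# Flatten/unflatten parameter lists so Adam state is a single vector.
nn_flatten <- function(p) {
  c(unlist(p$W, use.names = FALSE), unlist(p$b, use.names = FALSE),
    unname(p$beta), unname(p$alpha))
}

nn_unflatten <- function(v, skeleton) {
  out <- skeleton
  i <- 0L
  for (l in seq_along(skeleton$W)) {
    k <- length(skeleton$W[[l]])
    out$W[[l]][] <- v[i + seq_len(k)]; i <- i + k
  }
  for (l in seq_along(skeleton$b)) {
    k <- length(skeleton$b[[l]])
    out$b[[l]][] <- v[i + seq_len(k)]; i <- i + k
  }
  k <- length(skeleton$beta)
  out$beta <- v[i + seq_len(k)]; i <- i + k
  out$alpha <- v[i + seq_len(length(skeleton$alpha))]
  out
}

#' Fit a deep ordinal neural network (DONN)
#'
#' Fits the consistent-rank-logit ordinal model
#' \deqn{\log \frac{\Pr(Y_i > j \mid x_i)}{\Pr(Y_i \le j \mid x_i)} =
#'   \alpha_j + f(x_i)^\top \beta,}
#' where \eqn{f} is a multilayer ReLU feature map shared across the J-1
#' thresholds, \eqn{\beta} a single coefficient vector and \eqn{\alpha} the
#' per-threshold intercepts. The health score of an individual is the shared
#' linear predictor \eqn{f(x)^\top\beta}, without intercepts. Training
#' minimizes [donn_loss()] by minibatch Adam with early stopping on a
#' held-out validation split (best-epoch parameters are restored).
#'
#' Covariates are z-scored internally using training-set statistics, which
#' are stored and reused when scoring new data. With `hidden = integer(0)`
#' the feature map is the identity and the model is the proportional-odds
#' logit fitted by stochastic gradient descent (for J = 2, plain logistic
#' regression).
#'
#' @param x numeric covariate matrix (n x p).
#' @param y integer ordinal labels in `{0, ..., J-1}`; all J categories must
#'   be present.
#' @param J number of ordered categories; defaults to `max(y) + 1`.
#' @param hidden integer vector of hidden-layer widths (default `c(32, 16)`,
#'   two ReLU layers).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size minibatch size (default 100).
#' @param epochs maximum training epochs (default 150).
#' @param patience early-stopping patience in epochs (default 10); `Inf`
#'   disables early stopping.
#' @param validation_fraction fraction of rows held out for early stopping
#'   (default 0.1); 0 trains on all rows with no early stopping.
#' @param seed RNG seed controlling initialization, the validation split and
#'   minibatch order; fits are reproducible given it.
#' @param standardize z-score covariates with training statistics
#'   (default `TRUE`).
#' @param verbose print per-epoch losses.
#' @return an object of class `donn` with elements `params` (layer weights,
#'   `beta`, `alpha`), `J`, `p`, `center`/`scale`, `train_log` (per-epoch
#'   training and validation loss in the summed form), `best_epoch`, and the
#'   diagnostic flag `alpha_ordered` (whether the fitted intercepts are
#'   non-increasing, i.e. predicted exceedance curves are rank-consistent).
#' @seealso [predict.donn()], [health_score()], [binary_dnn()], [pom()]
#' @export
donn <- function(x, y, J = NULL, hidden = c(32L, 16L),
                 learning_rate = 0.001, batch_size = 100L, epochs = 150L,
                 patience = 10L, validation_fraction = 0.1, seed = 1L,
                 standardize = TRUE, verbose = FALSE) {
  x <- as_num_matrix(x)
  if (is.null(J)) J <- max(y) + 1L
  J <- as.integer(J)
  y <- check_labels(y, J)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < batch_size)
    stop(sprintf("n = %d is smaller than batch_size = %d", n, batch_size))
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop("validation_fraction must be in [0, 1)")
  missing_cat <- setdiff(0:(J - 1L), unique(y))
  if (length(missing_cat))
    stop(sprintf("category %s absent from training data",
                 paste(missing_cat, collapse = ", ")))
  hidden <- as.integer(hidden)

  center <- rep(0, p); scl <- rep(1, p)
  if (standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl < 1e-12] <- 1
  }
  xs <- sweep(sweep(x, 2L, center), 2L, scl, "/")

  with_seed(seed, {
    n_val <- if (validation_fraction > 0) max(1L, round(validation_fraction * n)) else 0L
    idx <- sample.int(n)
    val_idx <- if (n_val > 0L) idx[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(idx, val_idx)
    if (length(setdiff(0:(J - 1L), unique(y[tr_idx]))))
      stop("a category is absent from the training split; lower validation_fraction")
    Xtr <- xs[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- xs[val_idx, , drop = FALSE]; yval <- y[val_idx]
    enc_tr <- encode_levels(ytr, J)

    params <- nn_init(p, hidden, J)
    theta <- nn_flatten(params)
    m <- numeric(length(theta)); v <- numeric(length(theta))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
    ntr <- nrow(Xtr)
    best_val <- Inf; best_theta <- theta; best_epoch <- 0L; wait <- 0L
    log_train <- numeric(0); log_val <- numeric(0)

    for (epoch in seq_len(epochs)) {
      ord <- sample.int(ntr)
      for (start in seq(1L, ntr, by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1L, ntr)]
        g <- nn_grad(params, Xtr[rows, , drop = FALSE],
                     enc_tr[rows, , drop = FALSE])
        gv <- nn_flatten(g)
        t <- t + 1L
        m <- b1 * m + (1 - b1) * gv
        v <- b2 * v + (1 - b2) * gv * gv
        theta <- theta - learning_rate *
          (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
        params <- nn_unflatten(theta, params)
      }
      tr_loss <- donn_loss(nn_forward(params, Xtr), params$alpha, ytr)
      if (!is.finite(tr_loss))
        stop(sprintf("training loss diverged (NaN/Inf) at epoch %d", epoch))
      val_loss <- if (n_val > 0L)
        donn_loss(nn_forward(params, Xval), params$alpha, yval) else NA_real_
      log_train[epoch] <- tr_loss; log_val[epoch] <- val_loss
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %s", epoch, tr_loss,
                        if (is.na(val_loss)) "-" else sprintf("%.4f", val_loss)))
      if (n_val > 0L && is.finite(patience)) {
        if (val_loss < best_val - 1e-10) {
          best_val <- val_loss; best_theta <- theta
          best_epoch <- epoch; wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      } else {
        best_theta <- theta; best_epoch <- epoch
      }
    }
    if (n_val > 0L && is.finite(patience)) params <- nn_unflatten(best_theta, params)

    structure(list(
      params = params, J = J, p = p, hidden = hidden,
      center = center, scale = scl, standardize = standardize,
      train_log = data.frame(epoch = seq_along(log_train),
                             train_loss = log_train, val_loss = log_val),
      best_epoch = best_epoch,
      alpha_ordered = all(diff(params$alpha) <= 0),
      config = list(learning_rate = learning_rate, batch_size = batch_size,
                    epochs = epochs, patience = patience,
                    validation_fraction = validation_fraction, seed = seed),
      call = match.call()),
      class = "donn")
  })
}

scale_newdata <- function(object, x) {
  x <- as_num_matrix(x, "newdata")
  if (ncol(x) != object$p)
    stop(sprintf("newdata has %d columns; model expects %d", ncol(x), object$p))
  sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
}

#' Predictions from a fitted ordinal network
#'
#' @param object a fitted [donn()] model.
#' @param newdata covariate matrix with `object$p` columns.
#' @param type `"cumulative"` for the n x (J-1) matrix of exceedance
#'   probabilities \eqn{\Pr(Y > j)}, `"prob"` for the n x J category
#'   probabilities, `"class"` for the modal category, `"score"` for the
#'   shared health score \eqn{f(x)^\top\beta}.
#' @param ... unused.
#' @export
predict.donn <- function(object, newdata,
                         type = c("cumulative", "prob", "class", "score"),
                         ...) {
  type <- match.arg(type)
  xs <- scale_newdata(object, newdata)
  s <- nn_forward(object$params, xs)
  if (type == "score") return(s)
  cum <- stats::plogis(outer(s, object$params$alpha, "+"))
  colnames(cum) <- paste0("gt", 0:(object$J - 2L))
  if (type == "cumulative") return(cum)
  probs <- cbind(1, cum) - cbind(cum, 0)
  # unordered fitted intercepts can produce small negative cells; clamp
  probs <- pmax(probs, 0)
  probs <- probs / rowSums(probs)
  colnames(probs) <- paste0("cat", 0:(object$J - 1L))
  if (type == "prob") return(probs)
  as.integer(max.col(probs) - 1L)
}

#' Health score of individuals under a fitted axis model
#'
#' The shared linear predictor \eqn{f(x)^\top\beta} (network models) or
#' \eqn{x^\top\beta} (proportional odds), without threshold intercepts.
#' Higher scores indicate worse status on the axis under the `Y > j`
#' parameterization.
#'
#' @param object a fitted `donn` or `pom` model.
#' @param x covariate matrix.
#' @param ... passed to methods.
#' @return numeric vector with one score per row of `x`.
#' @export
health_score <- function(object, x, ...) UseMethod("health_score")

#' @rdname health_score
#' @export
health_score.donn <- function(object, x, ...) predict(object, x, type = "score")

#' @export
coef.donn <- function(object, ...) {
  list(alpha = object$params$alpha, beta = object$params$beta)
}

#' @export
print.donn <- function(x, ...) {
  cat(sprintf("Deep ordinal neural network (J = %d, p = %d)\n", x$J, x$p))
  arch <- if (length(x$hidden)) paste(x$hidden, collapse = "-") else "linear"
  cat(sprintf("  architecture: %s, score dim q = %d\n", arch,
              length(x$params$beta)))
  cat(sprintf("  alpha: %s (%s)\n",
              paste(format(round(x$params$alpha, 3)), collapse = ", "),
              if (x$alpha_ordered) "ordered" else "NOT ordered"))
  cat(sprintf("  trained %d epochs, best epoch %d\n",
              nrow(x$train_log), x$best_epoch))
  invisible(x)
}

#' @export
summary.donn <- function(object, ...) {
  tl <- object$train_log
  cat(sprintf("DONN fit: %d epochs run, best epoch %d\n",
              nrow(tl), object$best_epoch))
  cat(sprintf("  final train loss %.4f", tl$train_loss[nrow(tl)]))
  if (!all(is.na(tl$val_loss)))
    cat(sprintf(", best validation loss %.4f",
                min(tl$val_loss, na.rm = TRUE)))
  cat("\n")
  cat(sprintf("  intercepts ordered: %s\n", object$alpha_ordered))
  invisible(object)
}
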