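#' Specify the generating process for a synthetic cohort
#'
#' Defines a cohort with two partially overlapping covariate blocks — an
#' oxidative-stress block (default width 5: age, sex, smoking, white-blood-cell
#' and ALT analogues) and a metabolic-stress block (default width 6: age, sex,
#' BMI, triglyceride, HDL and fasting-glucose analogues) — and a 4-level
#' ordered outcome drawn from a cumulative-logit latent process
#' \deqn{\Pr(Y > j \mid x) = \sigma\{(\alpha_j + g(x)) / s\},}
#' where \eqn{g(x)} is linear in the true coefficients plus an optional
#' nonlinearity and \eqn{s} is the latent noise scale. The first two columns
#' of both blocks are the same draws (the shared age and sex analogues).
#'
#' Continuous covariates are standard normal; the sex and smoking analogues
#' are Bernoulli(1/2). With `nonlinearity = "quadratic"` the term
#' `nonlin_coef * x1^2` is added to \eqn{g}; with `"interaction"`,
#' `nonlin_coef * x1 * x2` (columns of the shared block).
#'
#' @param n_samples number of individuals.
#' @param n_categories number of ordered outcome levels \eqn{J \ge 2}.
#' @param seed integer RNG seed; generation is fully deterministic given it.
#' @param alpha_true threshold intercepts, length `n_categories - 1`,
#'   strictly decreasing (the `Y > j` parameterization).
#' @param beta_oxi_true,beta_meta_true true coefficient vectors for the two
#'   blocks; their lengths set the block widths.
#' @param nonlinearity one of `"none"`, `"quadratic"`, `"interaction"`.
#' @param nonlin_coef coefficient of the nonlinear term.
#' @param noise_scale positive scale of the latent logistic error; 1 gives
#'   the plain cumulative-logit model.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()], [true_cumulative_probs()]
#' @export
cohort_spec <- function(n_samples,
                        n_categories = 4L,
                        seed = 1L,
                        alpha_true = c(1, 0, -1),
                        beta_oxi_true = c(0.8, -0.5, 0.6, 0.4, -0.3),
                        beta_meta_true = c(0.8, -0.5, 0.5, -0.4, 0.3, 0.6),
                        nonlinearity = c("none", "quadratic", "interaction"),
                        nonlin_coef = 1,
                        noise_scale = 1) {
  nonlinearity <- match.arg(nonlinearity)
  n_samples <- as.integer(n_samples)
  J <- as.integer(n_categories)
  if (is.na(n_samples) || n_samples < 1L)
    stop("n_samples must be a positive integer")
  if (is.na(J) || J < 2L)
    stop("n_categories must be an integer >= 2")
  if (length(alpha_true) != J - 1L)
    stop(sprintf("alpha_true must have length n_categories - 1 = %d", J - 1L))
  if (J > 2L && any(diff(alpha_true) >= 0))
    stop("alpha_true must be strictly decreasing (monotone thresholds)")
  if (!is.numeric(noise_scale) || noise_scale <= 0)
    stop("noise_scale must be a positive real")
  structure(
    list(n_samples = n_samples, n_categories = J, seed = as.integer(seed),
         alpha_true = as.numeric(alpha_true),
         beta_oxi_true = as.numeric(beta_oxi_true),
         beta_meta_true = as.numeric(beta_meta_true),
         nonlinearity = nonlinearity, nonlin_coef = nonlin_coef,
         noise_scale = noise_scale),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  n = %d, J = %d, seed = %d\n",
              x$n_samples, x$n_categories, x$seed))
  cat(sprintf("  blocks: oxi p1 = %d, meta p2 = %d (first %d columns shared)\n",
              length(x$beta_oxi_true), length(x$beta_meta_true),
              n_shared_cols(x)))
  cat(sprintf("  alpha = (%s)\n", paste(format(x$alpha_true), collapse = ", ")))
  cat(sprintf("  nonlinearity = %s (coef %g), noise scale = %g\n",
              x$nonlinearity, x$nonlin_coef, x$noise_scale))
  invisible(x)
}

n_shared_cols <- function(spec) {
  min(2L, length(spec$beta_oxi_true), length(spec$beta_meta_true))
}

# Linear-plus-nonlinear predictor g(x) of the generating process.
cohort_g <- function(spec, X_oxi, X_meta) {
  g <- drop(X_oxi %*% spec$beta_oxi_true + X_meta %*% spec$beta_meta_true)
  if (spec$nonlinearity == "quadratic") {
    g <- g + spec$nonlin_coef * X_oxi[, 1L]^2
  } else if (spec$nonlinearity == "interaction") {
    if (ncol(X_oxi) < 2L) stop("interaction nonlinearity needs >= 2 columns")
    g <- g + spec$nonlin_coef * X_oxi[, 1L] * X_oxi[, 2L]
  }
  g
}

#' Generate a synthetic cohort
#'
#' Draws covariates and ordinal labels from the process defined by a
#' [cohort_spec()]. Labels are sampled by inverse-CDF with one uniform draw
#' per row: \eqn{y_i = \sum_j I\{u_i < \Pr(Y_i > j)\}}, which reproduces the
#' category probabilities exactly and is deterministic for a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `hs_cohort`: a list with numeric matrices
#'   `X_oxi` (n x p1), `X_meta` (n x p2), integer labels `y` in
#'   `{0, ..., J-1}` and the generating `spec`.
#' @examples
#' coh <- generate_cohort(cohort_spec(500, seed = 1))
#' table(coh$y)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  p1 <- length(spec$beta_oxi_true)
  p2 <- length(spec$beta_meta_true)
  ns <- n_shared_cols(spec)
  with_seed(spec$seed, {
    # shared columns: age analogue (normal), sex analogue (Bernoulli)
    shared <- cbind(stats::rnorm(n),
                    if (ns >= 2L) stats::rbinom(n, 1L, 0.5))
    shared <- shared[, seq_len(ns), drop = FALSE]
    own_oxi <- if (p1 > ns) {
      # smoking analogue binary, remaining continuous
      cbind(stats::rbinom(n, 1L, 0.5),
            if (p1 - ns > 1L)
              matrix(stats::rnorm(n * (p1 - ns - 1L)), nrow = n))
    }
    X_oxi <- cbind(shared, own_oxi)[, seq_len(p1), drop = FALSE]
    own_meta <- if (p2 > ns)
      matrix(stats::rnorm(n * (p2 - ns)), nrow = n)
    X_meta <- cbind(shared, own_meta)[, seq_len(p2), drop = FALSE]
    colnames(X_oxi) <- paste0("oxi_", seq_len(p1))
    colnames(X_meta) <- paste0("meta_", seq_len(p2))
    cum <- true_cumulative_probs(spec, X_oxi, X_meta)
    u <- stats::runif(n)
    y <- as.integer(rowSums(u < cum))
    structure(list(X_oxi = X_oxi, X_meta = X_meta, y = y, spec = spec),
              class = "hs_cohort")
  })
}

#' Exceedance probabilities of the generating process
#'
#' Returns the n x (J-1) matrix with entry (i, j) equal to
#' \eqn{\Pr(Y_i > j)} under the cumulative-logit process of `spec`, i.e. the
#' probabilities the labels were sampled from. Rows are non-increasing across
#' thresholds because the intercepts are strictly decreasing.
#'
#' @param spec a [cohort_spec()].
#' @param X_oxi,X_meta covariate matrices conforming to the spec's widths.
#' @return numeric matrix, rows in `[0, 1]`, non-increasing left to right.
#' @export
true_cumulative_probs <- function(spec, X_oxi, X_meta) {
  stopifnot(inherits(spec, "cohort_spec"))
  X_oxi <- as_num_matrix(X_oxi, "X_oxi")
  X_meta <- as_num_matrix(X_meta, "X_meta")
  p1 <- length(spec$beta_oxi_true); p2 <- length(spec$beta_meta_true)
  if (ncol(X_oxi) != p1 || ncol(X_meta) != p2)
    stop(sprintf("covariate widths (%d, %d) do not match spec (%d, %d)",
                 ncol(X_oxi), ncol(X_meta), p1, p2))
  if (nrow(X_oxi) != nrow(X_meta))
    stop("X_oxi and X_meta must have the same number of rows")
  g <- cohort_g(spec, X_oxi, X_meta)
  stats::plogis(outer(g, spec$alpha_true, "+") / spec$noise_scale)
}

#' @export
print.hs_cohort <- function(x, ...) {
  cat(sprintf("Synthetic health-space cohort: n = %d, J = %d\n",
              length(x$y), x$spec$n_categories %||% (max(x$y) + 1L)))
  cat(sprintf("  oxidation block: %d covariates; metabolic block: %d covariates\n",
              ncol(x$X_oxi), ncol(x$X_meta)))
  tab <- table(factor(x$y, levels = 0:max(x$y)))
  cat("  label census:", paste(sprintf("%s:%d", names(tab), tab),
                               collapse = "  "), "\n")
  invisible(x)
}
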