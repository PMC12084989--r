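#' Build the two-axis Health Space
#'
#' Combines one fitted axis model for oxidative stress and one for metabolic
#' stress into per-individual 2-D scores
#' \eqn{(\hat W_{oxi}\hat\beta_{oxi}, \hat W_{meta}\hat\beta_{meta})}. Raw
#' scores are the models' shared linear predictors; each axis is then
#' normalized to `[0, 1]`, either by training-set min-max (the default —
#' training scores attain 0 and 1 exactly; new data are clamped) or by a
#' sigmoid centred with the model's mean threshold intercept.
#'
#' Axis orientation: larger scores must mean worse status. If an axis's raw
#' score correlates negatively (Spearman) with the ordinal label rank, its
#' sign is flipped and the flip is recorded, so plots are comparable across
#' models.
#'
#' Normalization constants (and flips) are frozen at construction; scoring
#' an external cohort with [predict.health_space()] reuses them without
#' refitting, and clamped points are counted.
#'
#' @param model_oxi,model_meta fitted axis models ([donn()], [binary_dnn()]
#'   or [pom()]).
#' @param X_oxi,X_meta covariate matrices for the two axes (equal row count).
#' @param labels ordinal group labels for the rows.
#' @param normalizer `"minmax"` or `"sigmoid"`.
#' @param orient flip axes that anti-correlate with label rank
#'   (default `TRUE`).
#' @return an object of class `health_space`: raw and normalized score
#'   vectors, labels, the frozen `normalization` record (method, constants,
#'   flips, clamp counts) and the two axis models.
#' @seealso [pairwise_hsi()], [cluster_metrics()], [plot.health_space()]
#' @export
health_space <- function(model_oxi, model_meta, X_oxi, X_meta, labels,
                         normalizer = c("minmax", "sigmoid"),
                         orient = TRUE) {
  normalizer <- match.arg(normalizer)
  X_oxi <- as_num_matrix(X_oxi, "X_oxi")
  X_meta <- as_num_matrix(X_meta, "X_meta")
  if (nrow(X_oxi) != nrow(X_meta))
    stop("X_oxi and X_meta must have the same number of rows")
  if (length(labels) != nrow(X_oxi))
    stop("labels length must match the number of rows")
  raw_oxi <- health_score(model_oxi, X_oxi)
  raw_meta <- health_score(model_meta, X_meta)

  flip_axis <- function(raw) {
    if (!orient || stats::sd(raw) == 0) return(1)
    rho <- stats::cor(raw, as.numeric(labels), method = "spearman")
    if (!is.na(rho) && rho < 0) -1 else 1
  }
  flip_oxi <- flip_axis(raw_oxi); flip_meta <- flip_axis(raw_meta)
  raw_oxi <- raw_oxi * flip_oxi; raw_meta <- raw_meta * flip_meta

  make_norm <- function(raw, model) {
    if (normalizer == "minmax") {
      rng <- range(raw)
      if (diff(rng) < 1e-300) rng[2L] <- rng[1L] + 1
      list(constants = c(min = rng[1L], max = rng[2L]),
           fn = function(r) pmin(1, pmax(0, (r - rng[1L]) / diff(rng))))
    } else {
      off <- mean(model_alpha(model))
      list(constants = c(offset = off),
           fn = function(r) stats::plogis(r + off))
    }
  }
  nrm_oxi <- make_norm(raw_oxi, model_oxi)
  nrm_meta <- make_norm(raw_meta, model_meta)

  structure(list(
    raw_oxi = raw_oxi, raw_meta = raw_meta,
    norm_oxi = nrm_oxi$fn(raw_oxi), norm_meta = nrm_meta$fn(raw_meta),
    labels = as.integer(labels),
    normalization = list(method = normalizer,
                         oxi = nrm_oxi$constants, meta = nrm_meta$constants,
                         flip_oxi = flip_oxi, flip_meta = flip_meta,
                         clamped = c(oxi = 0L, meta = 0L)),
    normalizers = list(oxi = nrm_oxi$fn, meta = nrm_meta$fn),
    models = list(oxi = model_oxi, meta = model_meta)),
    class = "health_space")
}

model_alpha <- function(model) {
  if (inherits(model, "donn")) model$params$alpha else model$alpha
}

#' Score an external cohort in a fitted Health Space
#'
#' Applies the frozen axis models, orientation flips and normalization
#' constants of an existing [health_space()] to new data — the models are
#' never refitted, mirroring external validation. Points falling outside the
#' training score range are clamped to `[0, 1]` and counted in the returned
#' object's `normalization$clamped`.
#'
#' @param object a fitted `health_space`.
#' @param X_oxi,X_meta covariates of the new cohort.
#' @param labels ordinal labels of the new cohort.
#' @param ... unused.
#' @return a new `health_space` for the external cohort.
#' @export
predict.health_space <- function(object, X_oxi, X_meta, labels, ...) {
  nz <- object$normalization
  raw_oxi <- health_score(object$models$oxi, X_oxi) * nz$flip_oxi
  raw_meta <- health_score(object$models$meta, X_meta) * nz$flip_meta
  norm_oxi <- object$normalizers$oxi(raw_oxi)
  norm_meta <- object$normalizers$meta(raw_meta)
  clamped <- c(oxi = 0L, meta = 0L)
  if (nz$method == "minmax") {
    clamped <- c(
      oxi = sum(raw_oxi < nz$oxi["min"] | raw_oxi > nz$oxi["max"]),
      meta = sum(raw_meta < nz$meta["min"] | raw_meta > nz$meta["max"]))
    if (sum(clamped) > 0)
      message(sprintf("clamped %d oxidation and %d metabolism scores to [0, 1]",
                      clamped[["oxi"]], clamped[["meta"]]))
  }
  out <- object
  out$raw_oxi <- raw_oxi; out$raw_meta <- raw_meta
  out$norm_oxi <- norm_oxi; out$norm_meta <- norm_meta
  out$labels <- as.integer(labels)
  out$normalization$clamped <- clamped
  out
}

#' @export
as.matrix.health_space <- function(x, which = c("norm", "raw"), ...) {
  which <- match.arg(which)
  if (which == "norm") cbind(oxi = x$norm_oxi, meta = x$norm_meta)
  else cbind(oxi = x$raw_oxi, meta = x$raw_meta)
}

#' @export
print.health_space <- function(x, ...) {
  cat(sprintf("Health space scores: n = %d, %d groups, normalizer = %s\n",
              length(x$labels), length(unique(x$labels)),
              x$normalization$method))
  if (x$normalization$flip_oxi < 0 || x$normalization$flip_meta < 0)
    cat(sprintf("  axis flips: oxi %s, meta %s\n",
                x$normalization$flip_oxi, x$normalization$flip_meta))
  cl <- x$normalization$clamped
  if (sum(cl) > 0)
    cat(sprintf("  clamped points: oxi %d, meta %d\n", cl[["oxi"]],
                cl[["meta"]]))
  invisible(x)
}

#' Health-space scatter plot
#'
#' Plots individuals in the (oxidation score, metabolism score) plane,
#' colored by ordinal group. Healthy individuals concentrate in the lower
#' left and the sickest group in the upper right when the axis models
#' separate the groups well. Normalized axes are fixed to `[0, 1]`.
#'
#' @param x a `health_space` object.
#' @param which plot normalized (default) or raw scores.
#' @param pch,cex,main usual graphical parameters.
#' @param legend_pos legend position keyword, or `NA` to suppress.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the data frame of plotted coordinates and labels.
#' @export
plot.health_space <- function(x, which = c("norm", "raw"), pch = 16,
                              cex = 0.5, main = "Health space",
                              legend_pos = "topleft", ...) {
  which <- match.arg(which)
  pts <- as.matrix(x, which = which)
  groups <- sort(unique(x$labels))
  pal <- grDevices::hcl.colors(max(length(groups), 2L), "Dark 3")
  col <- pal[match(x$labels, groups)]
  lims <- if (which == "norm") c(0, 1) else NULL
  graphics::plot(pts[, 1L], pts[, 2L], col = col, pch = pch, cex = cex,
                 xlab = "Oxidation score", ylab = "Metabolism score",
                 xlim = lims, ylim = lims, main = main, ...)
  if (!is.na(legend_pos) && length(groups))
    graphics::legend(legend_pos, legend = paste("group", groups),
                     col = pal[seq_along(groups)], pch = pch, cex = 0.8,
                     bty = "n")
  invisible(data.frame(oxi = pts[, 1L], meta = pts[, 2L], label = x$labels))
}
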