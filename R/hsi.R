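#' Fit a 2-D confidence ellipse to a point cloud
#'
#' The ellipse is the set \eqn{\{z : (z - c)^\top \Sigma^{-1} (z - c) \le
#' \chi^2_2(\mathrm{level})\}} with `c` the sample mean and `Sigma` the
#' sample covariance — the region that would contain a given fraction of the
#' mass if the points were Gaussian. A singular covariance (collinear
#' points) is ridged by `1e-8` on the diagonal with a warning so degenerate
#' groups still yield a region.
#'
#' @param points m x 2 numeric matrix, m >= 3.
#' @param level confidence level in (0, 1), default 0.95.
#' @return an object of class `confidence_ellipse` with `center`, `cov`,
#'   `level` and the squared Mahalanobis radius `radius2`.
#' @export
fit_ellipse <- function(points, level = 0.95) {
  points <- as_num_matrix(points, "points")
  if (ncol(points) != 2L) stop("points must have exactly 2 columns")
  if (nrow(points) < 3L)
    stop("at least 3 points are required to fit a confidence ellipse")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  ctr <- colMeans(points)
  S <- stats::cov(points)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) {
    warning("singular covariance; adding ridge 1e-8 to the diagonal")
    S <- S + diag(1e-8, 2L)
  }
  structure(list(center = ctr, cov = S, level = level,
                 radius2 = stats::qchisq(level, df = 2L)),
            class = "confidence_ellipse")
}

#' @export
print.confidence_ellipse <- function(x, ...) {
  cat(sprintf("Confidence ellipse (level %.2f): center (%.3f, %.3f), area %.4g\n",
              x$level, x$center[1L], x$center[2L], ellipse_area(x)))
  invisible(x)
}

#' Area of a confidence ellipse
#' @param e a `confidence_ellipse`.
#' @return \eqn{\pi \sqrt{\det\Sigma}\, \chi^2_2(\mathrm{level})}.
#' @export
ellipse_area <- function(e) {
  pi * sqrt(max(det(e$cov), 0)) * e$radius2
}

# axis-aligned bounding box: center +/- sqrt(radius2 * diag(Sigma))
ellipse_bbox <- function(e) {
  half <- sqrt(e$radius2 * diag(e$cov))
  rbind(lo = e$center - half, hi = e$center + half)
}

# indicator of membership for an n x 2 matrix of points
in_ellipse <- function(e, pts) {
  stats::mahalanobis(pts, e$center, e$cov) <= e$radius2
}

#' Jaccard overlap of two confidence ellipses
#'
#' Computes `area(e1 ∩ e2) / area(e1 ∪ e2)` by numerical integration of the
#' two membership indicators. The `"grid"` method evaluates them on a
#' `resolution` x `resolution` lattice over the union bounding box (padded
#' 5%); its error is O(1/resolution) of the box scale. The `"montecarlo"`
#' method samples `n_points` uniform points on the same box under a fixed
#' seed; its standard error is about `sqrt(J(1-J)/n_eff)`. Disjoint bounding
#' boxes short-circuit to 0 exactly.
#'
#' @param e1,e2 `confidence_ellipse` objects.
#' @param method `"grid"` (default) or `"montecarlo"`.
#' @param resolution grid points per axis (default 512).
#' @param n_points Monte-Carlo sample size (default 2e5).
#' @param seed Monte-Carlo seed.
#' @return overlap in `[0, 1]`.
#' @export
ellipse_jaccard <- function(e1, e2, method = c("grid", "montecarlo"),
                            resolution = 512L, n_points = 2e5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(e1, "confidence_ellipse"),
            inherits(e2, "confidence_ellipse"))
  b1 <- ellipse_bbox(e1); b2 <- ellipse_bbox(e2)
  # disjoint bounding boxes -> disjoint ellipses
  if (any(b1["hi", ] < b2["lo", ]) || any(b2["hi", ] < b1["lo", ]))
    return(0)
  lo <- pmin(b1["lo", ], b2["lo", ]); hi <- pmax(b1["hi", ], b2["hi", ])
  pad <- 0.05 * (hi - lo)
  lo <- lo - pad; hi <- hi + pad
  pts <- if (method == "grid") {
    xs <- seq(lo[1L], hi[1L], length.out = resolution)
    ys <- seq(lo[2L], hi[2L], length.out = resolution)
    cbind(rep(xs, times = resolution), rep(ys, each = resolution))
  } else {
    with_seed(seed, cbind(stats::runif(n_points, lo[1L], hi[1L]),
                          stats::runif(n_points, lo[2L], hi[2L])))
  }
  i1 <- in_ellipse(e1, pts); i2 <- in_ellipse(e2, pts)
  union <- sum(i1 | i2)
  if (union == 0L) return(0)
  sum(i1 & i2) / union
}

#' Health Space Index from pairwise ellipse separation
#'
#' For every pair of ordinal groups, fits a confidence ellipse to each
#' group's 2-D scores and computes `HSI = 1 - Jaccard(e_a, e_b)`, oriented
#' so that higher values mean better group separation (1 = disjoint
#' ellipses, 0 = identical). The model-level summary is the unweighted mean
#' over the J(J-1)/2 pairs — six for four groups. Groups with fewer than 3
#' points are excluded with a warning and their pairs reported as `NA`.
#'
#' @param x a [health_space()] object (normalized scores are used) or an
#'   n x 2 matrix of scores.
#' @param labels group labels (taken from `x` when it is a `health_space`).
#' @param level ellipse confidence level, default 0.95.
#' @param method,resolution,n_points,seed passed to [ellipse_jaccard()].
#' @return an object of class `hsi_result`: symmetric `pairwise` HSI matrix
#'   (diagonal `NA`), the matching `jaccard` matrix, the `average` HSI, the
#'   pair table and the fitted ellipses.
#' @export
pairwise_hsi <- function(x, labels = NULL, level = 0.95,
                         method = c("grid", "montecarlo"),
                         resolution = 512L, n_points = 2e5, seed = 1L) {
  method <- match.arg(method)
  if (inherits(x, "health_space")) {
    labels <- x$labels
    pts <- as.matrix(x)
  } else {
    pts <- as_num_matrix(x, "x")
    if (is.null(labels)) stop("labels are required for matrix input")
  }
  if (ncol(pts) != 2L) stop("scores must be 2-dimensional")
  labels <- as.vector(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("at least 2 groups are required")
  sizes <- vapply(groups, function(g) sum(labels == g), integer(1))
  usable <- sizes >= 3L
  if (any(!usable))
    warning(sprintf("group(s) %s have < 3 points and are excluded",
                    paste(groups[!usable], collapse = ", ")))
  ellipses <- stats::setNames(vector("list", length(groups)),
                              as.character(groups))
  for (k in which(usable))
    ellipses[[k]] <- fit_ellipse(pts[labels == groups[k], , drop = FALSE],
                                 level = level)
  G <- length(groups)
  jac <- matrix(NA_real_, G, G, dimnames = list(groups, groups))
  for (a in seq_len(G - 1L)) for (b in (a + 1L):G) {
    if (usable[a] && usable[b]) {
      jac[a, b] <- jac[b, a] <- ellipse_jaccard(
        ellipses[[a]], ellipses[[b]], method = method,
        resolution = resolution, n_points = n_points, seed = seed)
    }
  }
  hsi <- 1 - jac
  up <- upper.tri(hsi)
  pair_tab <- data.frame(
    group_a = groups[row(hsi)[up]], group_b = groups[col(hsi)[up]],
    jaccard = jac[up], hsi = hsi[up])
  structure(list(pairwise = hsi, jaccard = jac,
                 average = mean(hsi[up], na.rm = TRUE),
                 pairs = pair_tab, ellipses = ellipses,
                 level = level, method = method),
            class = "hsi_result")
}

#' @export
print.hsi_result <- function(x, digits = 3, ...) {
  cat(sprintf("Health Space Index (level %.2f, %s overlap)\n",
              x$level, x$method))
  cat(sprintf("  average HSI over %d pairs: %.4f\n",
              nrow(x$pairs), x$average))
  print(round(x$pairwise, digits))
  invisible(x)
}
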