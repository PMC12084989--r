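#' Clustering validity indices on health-space scores
#'
#' Three auxiliary measures of how well the ordinal groups separate in the
#' 2-D score plane, with the groups taken as given cluster labels (never
#' inferred). All use the Euclidean metric.
#'
#' * `silhouette_score()`: mean over points of \eqn{(b - a)/\max(a, b)},
#'   where `a` is the mean distance to the point's own cluster (excluding
#'   itself) and `b` the smallest mean distance to another cluster; in
#'   \eqn{[-1, 1]}, higher is better. Points in singleton clusters
#'   contribute 0.
#' * `davies_bouldin()`: mean over clusters of the worst similarity ratio
#'   \eqn{\max_{j \ne i} (\sigma_i + \sigma_j)/d(c_i, c_j)}, with
#'   \eqn{\sigma} the mean member-to-centroid distance; \eqn{\ge 0}, lower
#'   is better. Coincident centroids make the ratio infinite and are
#'   reported as an error naming the pair.
#' * `calinski_harabasz()`: \eqn{[\mathrm{tr}(B)/(k-1)] /
#'   [\mathrm{tr}(W)/(n-k)]} with `B`, `W` the between/within scatter
#'   matrices; \eqn{\ge 0}, higher is better; zero within-dispersion gives
#'   `Inf` with a warning.
#'
#' @param points n x d numeric matrix (d = 2 for health-space scores).
#' @param labels cluster labels, at least 2 distinct values.
#' @return a single number; `cluster_metrics()` returns all three in a
#'   `metrics_report` list along with `n` and the number of groups.
#' @name cluster_metrics
NULL

check_clusters <- function(points, labels, min_groups = 2L) {
  points <- as_num_matrix(points, "points")
  if (length(labels) != nrow(points))
    stop("labels length must match the number of points")
  f <- factor(labels)
  if (nlevels(f) < min_groups)
    stop(if (min_groups == 2L && nlevels(f) == 1L)
      "Silhouette undefined for one cluster" else
        sprintf("at least %d groups are required", min_groups))
  list(points = points, f = f)
}

# Row-chunked Euclidean distances keep memory linear in n for large cohorts.
# Direct coordinate differencing (not the x^2+y^2-2xy expansion) so the
# result agrees with dist() to full float precision; cheap at d = 2.
cross_dist <- function(A, B) {
  d2 <- outer(A[, 1L], B[, 1L], "-")^2
  for (j in seq_len(ncol(A))[-1L])
    d2 <- d2 + outer(A[, j], B[, j], "-")^2
  sqrt(d2)
}

#' @rdname cluster_metrics
#' @export
silhouette_score <- function(points, labels) {
  cl <- check_clusters(points, labels)
  pts <- cl$points; f <- cl$f
  n <- nrow(pts); k <- nlevels(f)
  sizes <- tabulate(f, k)
  idx <- split(seq_len(n), f)
  s <- numeric(n)
  chunk <- 1024L
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    D <- cross_dist(pts[rows, , drop = FALSE], pts)
    # mean distance from each chunk row to every cluster
    md <- vapply(seq_len(k), function(c)
      rowSums(D[, idx[[c]], drop = FALSE]), numeric(length(rows)))
    md <- matrix(md, nrow = length(rows))
    own <- as.integer(f[rows])
    for (r in seq_along(rows)) {
      c0 <- own[r]
      if (sizes[c0] == 1L) { s[rows[r]] <- 0; next }
      a <- md[r, c0] / (sizes[c0] - 1L)     # exclude self (distance 0)
      b <- min(md[r, -c0] / sizes[-c0])
      s[rows[r]] <- (b - a) / max(a, b)
    }
  }
  mean(s)
}

#' @rdname cluster_metrics
#' @export
davies_bouldin <- function(points, labels) {
  cl <- check_clusters(points, labels)
  pts <- cl$points; f <- cl$f
  k <- nlevels(f)
  cent <- t(vapply(levels(f), function(g)
    colMeans(pts[f == g, , drop = FALSE]), numeric(ncol(pts))))
  sig <- vapply(seq_len(k), function(c) {
    m <- pts[f == levels(f)[c], , drop = FALSE]
    mean(sqrt(rowSums(sweep(m, 2L, cent[c, ])^2)))
  }, numeric(1))
  Dc <- cross_dist(cent, cent)
  r <- numeric(k)
  for (i in seq_len(k)) {
    ratio <- (sig[i] + sig[-i]) / Dc[i, -i]
    if (any(!is.finite(ratio))) {
      j <- setdiff(seq_len(k), i)[which(!is.finite(ratio))[1L]]
      stop(sprintf("coincident centroids for clusters '%s' and '%s'",
                   levels(f)[i], levels(f)[j]))
    }
    r[i] <- max(ratio)
  }
  mean(r)
}

#' @rdname cluster_metrics
#' @export
calinski_harabasz <- function(points, labels) {
  cl <- check_clusters(points, labels)
  pts <- cl$points; f <- cl$f
  n <- nrow(pts); k <- nlevels(f)
  if (n <= k) stop("need more points than clusters")
  gmean <- colMeans(pts)
  Wtr <- 0; Btr <- 0
  for (g in levels(f)) {
    m <- pts[f == g, , drop = FALSE]
    cg <- colMeans(m)
    Wtr <- Wtr + sum(sweep(m, 2L, cg)^2)
    Btr <- Btr + nrow(m) * sum((cg - gmean)^2)
  }
  if (Wtr == 0) {
    warning("zero within-cluster dispersion; index is infinite")
    return(Inf)
  }
  (Btr / (k - 1)) / (Wtr / (n - k))
}

#' @rdname cluster_metrics
#' @param x a `health_space` object or a points matrix.
#' @export
cluster_metrics <- function(x, labels = NULL) {
  if (inherits(x, "health_space")) {
    labels <- x$labels
    x <- as.matrix(x)
  }
  structure(list(silhouette = silhouette_score(x, labels),
                 davies_bouldin = davies_bouldin(x, labels),
                 calinski_harabasz = calinski_harabasz(x, labels),
                 n_samples = nrow(x),
                 n_groups = length(unique(labels))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Clustering validity (n = %d, %d groups)\n",
              x$n_samples, x$n_groups))
  cat(sprintf("  silhouette:        %8.4f  (higher better)\n", x$silhouette))
  cat(sprintf("  Davies-Bouldin:    %8.4f  (lower better)\n",
              x$davies_bouldin))
  cat(sprintf("  Calinski-Harabasz: %8.2f  (higher better)\n",
              x$calinski_harabasz))
  invisible(x)
}
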