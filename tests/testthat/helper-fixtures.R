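# Shared fixtures and independent oracles, all built in code.

# Small default cohort used across tests.
small_cohort <- function(n = 1200, seed = 1, ...) {
  generate_cohort(cohort_spec(n, seed = seed, ...))
}

# Fast network settings for unit tests (the defaults are for full runs).
fast_fit <- function(epochs = 25, seed = 1, ...) {
  list(epochs = epochs, seed = seed, ...)
}

# k tight Gaussian point clouds at given 2-D centers.
make_clusters <- function(centers, m = 10, spread = 0.01, seed = 1) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(m, centers[i, 1], spread), rnorm(m, centers[i, 2], spread))))
  list(points = pts, labels = rep(seq_len(nrow(centers)) - 1L, each = m))
}

## ---- brute-force clustering oracles (independent of the package code) ----

oracle_silhouette <- function(pts, labels) {
  n <- nrow(pts)
  D <- as.matrix(dist(pts))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_davies_bouldin <- function(pts, labels) {
  gs <- sort(unique(labels))
  cent <- t(sapply(gs, function(g) colMeans(pts[labels == g, , drop = FALSE])))
  sig <- sapply(seq_along(gs), function(c) {
    m <- pts[labels == gs[c], , drop = FALSE]
    mean(sqrt(rowSums(sweep(m, 2, cent[c, ])^2)))
  })
  k <- length(gs)
  mean(sapply(seq_len(k), function(i)
    max(sapply(setdiff(seq_len(k), i), function(j)
      (sig[i] + sig[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))))))
}

oracle_calinski_harabasz <- function(pts, labels) {
  gs <- sort(unique(labels))
  n <- nrow(pts); k <- length(gs)
  gm <- colMeans(pts)
  W <- 0; B <- 0
  for (g in gs) {
    m <- pts[labels == g, , drop = FALSE]
    cg <- colMeans(m)
    W <- W + sum(sweep(m, 2, cg)^2)
    B <- B + nrow(m) * sum((cg - gm)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# Closed-form lens area of two circles of radius r at center distance d.
circle_lens_area <- function(r, d) {
  if (d >= 2 * r) return(0)
  2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
}

# Build a confidence_ellipse directly from known center/covariance.
ellipse_from <- function(center, cov, level = 0.95) {
  structure(list(center = center, cov = cov, level = level,
                 radius2 = qchisq(level, 2)),
            class = "confidence_ellipse")
}

# Circle-shaped ellipse of exact radius r (covariance scaled so that the
# chi-square radius equals r).
circle_ellipse <- function(center, r, level = 0.95) {
  ellipse_from(center, diag(r^2 / qchisq(level, 2), 2), level)
}
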