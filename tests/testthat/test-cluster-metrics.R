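test_that("all three indices match brute-force oracles exactly", {
  set.seed(61)
  for (rep in 1:3) {
    pts <- matrix(rnorm(400), ncol = 2)
    labels <- sample(0:3, 200, replace = TRUE)
    expect_equal(silhouette_score(pts, labels),
                 oracle_silhouette(pts, labels), tolerance = 1e-10)
    expect_equal(davies_bouldin(pts, labels),
                 oracle_davies_bouldin(pts, labels), tolerance = 1e-10)
    expect_equal(calinski_harabasz(pts, labels),
                 oracle_calinski_harabasz(pts, labels), tolerance = 1e-10)
  }
  # 12-point fixture with uneven groups and a singleton
  pts12 <- matrix(c(0, 0, 1, 0, 0, 1, 5, 5, 6, 5, 5, 6, 9, 0, 10, 0, 9, 1,
                    0, 9, 1, 9, 20, 20), ncol = 2, byrow = TRUE)
  lab12 <- c(0, 0, 0, 1, 1, 1, 2, 2, 2, 3, 3, 4)
  expect_equal(silhouette_score(pts12, lab12),
               oracle_silhouette(pts12, lab12), tolerance = 1e-10)
  expect_equal(davies_bouldin(pts12, lab12),
               oracle_davies_bouldin(pts12, lab12), tolerance = 1e-10)
  expect_equal(calinski_harabasz(pts12, lab12),
               oracle_calinski_harabasz(pts12, lab12), tolerance = 1e-10)
})

test_that("silhouette agrees with the cluster package on a random fixture", {
  set.seed(62)
  pts <- matrix(rnorm(300), ncol = 2)
  labels <- sample(1:3, 150, replace = TRUE)
  sil <- cluster::silhouette(labels, dist(pts))
  expect_equal(silhouette_score(pts, labels), mean(sil[, "sil_width"]),
               tolerance = 1e-10)
})

test_that("well-separated tight clusters score near their ideals", {
  cl <- make_clusters(rbind(c(0, 0), c(100, 0)), m = 10, spread = 0.01,
                      seed = 63)
  expect_gt(silhouette_score(cl$points, cl$labels), 0.99)
  expect_lt(davies_bouldin(cl$points, cl$labels), 0.01)
  expect_gt(calinski_harabasz(cl$points, cl$labels), 1e6)
})

test_that("random labels on one blob give near-zero silhouette", {
  set.seed(64)
  pts <- matrix(rnorm(1000), ncol = 2)
  labels <- sample(0:3, 500, replace = TRUE)
  expect_lt(abs(silhouette_score(pts, labels)), 0.1)
})

test_that("Davies-Bouldin grows as clusters approach", {
  vals <- vapply(c(20, 10, 5, 3), function(d) {
    cl <- make_clusters(rbind(c(0, 0), c(d, 0)), m = 30, spread = 0.5,
                        seed = 65)
    davies_bouldin(cl$points, cl$labels)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("Calinski-Harabasz is scale-invariant and grows with separation", {
  cl <- make_clusters(rbind(c(0, 0), c(4, 0), c(0, 4)), m = 25, spread = 0.7,
                      seed = 66)
  v1 <- calinski_harabasz(cl$points, cl$labels)
  expect_equal(calinski_harabasz(cl$points * 17.3, cl$labels), v1,
               tolerance = 1e-10)
  pulled <- cl$points
  pulled[cl$labels == 1, 1] <- pulled[cl$labels == 1, 1] + 5
  expect_gt(calinski_harabasz(pulled, cl$labels), v1)
})

test_that("indices are translation and rotation invariant", {
  cl <- make_clusters(rbind(c(0, 0), c(3, 1), c(1, 3)), m = 20, spread = 0.6,
                      seed = 67)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- cl$points %*% R + matrix(c(11, -4), nrow(cl$points), 2,
                                    byrow = TRUE)
  expect_equal(silhouette_score(moved, cl$labels),
               silhouette_score(cl$points, cl$labels), tolerance = 1e-8)
  expect_equal(davies_bouldin(moved, cl$labels),
               davies_bouldin(cl$points, cl$labels), tolerance = 1e-8)
  expect_equal(calinski_harabasz(moved, cl$labels),
               calinski_harabasz(cl$points, cl$labels), tolerance = 1e-8)
})

test_that("degenerate inputs raise the documented errors", {
  pts <- matrix(rnorm(20), ncol = 2)
  expect_error(silhouette_score(pts, rep(0, 10)), "one cluster")
  # coincident centroids
  sq <- rbind(c(-1, -1), c(1, 1), c(-1, 1), c(1, -1))
  expect_error(davies_bouldin(sq, c(0, 0, 1, 1)), "coincident")
  # zero within-dispersion
  atoms <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5), c(9, 1))
  expect_warning(v <- calinski_harabasz(atoms[1:4, ], c(0, 0, 1, 1)),
                 "infinite")
  expect_identical(v, Inf)
})
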