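test_that("ellipse of a standard normal sample is close to the chi-square circle", {
  set.seed(51)
  pts <- matrix(rnorm(40000), ncol = 2)
  e <- fit_ellipse(pts, level = 0.95)
  expect_equal(e$radius2, qchisq(0.95, 2), tolerance = 1e-12) # ~5.991
  expect_equal(unname(e$center), c(0, 0), tolerance = 0.05)
  expect_equal(unname(e$cov), diag(2), tolerance = 0.05)
  expect_equal(ellipse_area(e), pi * qchisq(0.95, 2), tolerance = 0.05)
})

test_that("ellipses are affine-equivariant under translation", {
  set.seed(52)
  pts <- matrix(rnorm(200), ncol = 2)
  e0 <- fit_ellipse(pts)
  e1 <- fit_ellipse(sweep(pts, 2, c(-3, 7), "+"))
  expect_equal(unname(e1$center - e0$center), c(-3, 7), tolerance = 1e-10)
  expect_equal(e1$cov, e0$cov, tolerance = 1e-10)
})

test_that("degenerate point sets are rejected or ridged", {
  expect_error(fit_ellipse(matrix(rnorm(4), 2, 2)), "3 points")
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  e <- fit_ellipse(tri)
  expect_true(healthspace:::in_ellipse(e, matrix(colMeans(tri), 1)))
  coll <- cbind(1:5, 2 * (1:5))          # collinear
  expect_warning(e2 <- fit_ellipse(coll), "ridge")
  expect_gt(min(eigen(e2$cov)$values), 0)
})

test_that("jaccard limits: identical ellipses give 1, distant give 0", {
  e <- ellipse_from(c(0, 0), diag(2))
  expect_equal(ellipse_jaccard(e, e, resolution = 512), 1, tolerance = 1 / 256)
  far <- ellipse_from(c(1000, 0), diag(2))
  expect_identical(ellipse_jaccard(e, far), 0)
  expect_identical(ellipse_jaccard(e, far, method = "montecarlo"), 0)
})

test_that("circle overlap matches the analytic lens-area formula", {
  r <- 1
  for (d in c(0.5, 1, 1.5)) {
    e1 <- circle_ellipse(c(0, 0), r)
    e2 <- circle_ellipse(c(d, 0), r)
    lens <- circle_lens_area(r, d)
    truth <- lens / (2 * pi * r^2 - lens)
    expect_lt(abs(ellipse_jaccard(e1, e2, resolution = 1024) - truth), 0.005)
    expect_lt(abs(ellipse_jaccard(e1, e2, method = "montecarlo",
                                  n_points = 4e5, seed = 3) - truth), 0.005)
  }
})

test_that("grid and Monte-Carlo overlap agree at documented settings", {
  set.seed(53)
  for (k in 1:3) {
    A <- matrix(rnorm(4), 2); S1 <- crossprod(A) + diag(0.2, 2)
    B <- matrix(rnorm(4), 2); S2 <- crossprod(B) + diag(0.2, 2)
    e1 <- ellipse_from(c(0, 0), S1)
    e2 <- ellipse_from(runif(2, -1, 1), S2)
    j_grid <- ellipse_jaccard(e1, e2, resolution = 512)
    j_mc <- ellipse_jaccard(e1, e2, method = "montecarlo",
                            n_points = 2e5, seed = k)
    expect_lt(abs(j_grid - j_mc), 0.01)
  }
})

test_that("pairwise HSI has its limiting values and pair count", {
  cl <- make_clusters(rbind(c(0, 0), c(0, 0)), m = 200, spread = 1, seed = 54)
  # two groups drawn from the same cloud: near-total overlap
  h_same <- pairwise_hsi(cl$points, cl$labels, resolution = 256)
  expect_lt(h_same$pairwise[1, 2], 0.1)
  far <- make_clusters(rbind(c(0, 0), c(1000, 0)), m = 50, spread = 1)
  h_far <- pairwise_hsi(far$points, far$labels)
  expect_identical(h_far$pairwise[1, 2], 1)
  four <- make_clusters(rbind(c(0, 0), c(3, 0), c(0, 3), c(3, 3)),
                        m = 40, spread = 1, seed = 55)
  h4 <- pairwise_hsi(four$points, four$labels, resolution = 256)
  expect_identical(nrow(h4$pairs), 6L)            # J=4 -> 6 pairs
  expect_true(all(h4$pairs$hsi >= 0 & h4$pairs$hsi <= 1))
  expect_equal(h4$average, mean(h4$pairwise[upper.tri(h4$pairwise)]))
  expect_equal(h4$pairwise, t(h4$pairwise))
  expect_equal(h4$pairs$hsi, 1 - h4$pairs$jaccard)
})

test_that("HSI is invariant to a common affine map of all points", {
  four <- make_clusters(rbind(c(0, 0), c(2, 1), c(1, 3), c(3, 3)),
                        m = 60, spread = 0.8, seed = 56)
  A <- matrix(c(1.4, 0.5, -0.3, 0.9), 2)   # nonsingular
  shifted <- four$points %*% t(A) + matrix(c(5, -2), nrow(four$points), 2,
                                           byrow = TRUE)
  h0 <- pairwise_hsi(four$points, four$labels, resolution = 512)
  h1 <- pairwise_hsi(shifted, four$labels, resolution = 512)
  expect_true(all(abs(h0$pairs$hsi - h1$pairs$hsi) < 0.01))
})

test_that("moving a group away never decreases its pairwise HSI", {
  base <- make_clusters(rbind(c(0, 0), c(0, 0)), m = 80, spread = 1, seed = 57)
  shifts <- seq(0, 6, by = 1)
  vals <- vapply(shifts, function(d) {
    pts <- base$points
    pts[base$labels == 1, 1] <- pts[base$labels == 1, 1] + d
    pairwise_hsi(pts, base$labels, resolution = 512)$pairwise[1, 2]
  }, numeric(1))
  expect_true(all(diff(vals) > -0.01))   # non-decreasing within grid tolerance
  expect_equal(vals[length(vals)], 1)
})

test_that("small groups are excluded with a warning, pairs reported missing", {
  pts <- rbind(make_clusters(rbind(c(0, 0), c(5, 5)), m = 20, seed = 58)$points,
               c(9, 9), c(9.1, 9))
  labels <- c(rep(0, 20), rep(1, 20), 2, 2)
  expect_warning(h <- pairwise_hsi(pts, labels, resolution = 128), "exclud")
  expect_true(is.na(h$pairwise["0", "2"]))
  expect_false(is.na(h$pairwise["0", "1"]))
  expect_error(pairwise_hsi(pts, rep(0, nrow(pts))), "2 groups")
})
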