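test_that("encode_levels matches the exhaustive I(y > j) truth table", {
  expect_equal(unname(encode_levels(2, 4)), matrix(c(1, 1, 0), 1))
  expect_equal(unname(encode_levels(0, 4)), matrix(c(0, 0, 0), 1))
  expect_equal(unname(encode_levels(3, 4)), matrix(c(1, 1, 1), 1))
  y <- 0:3
  enc <- encode_levels(y, 4)
  oracle <- sapply(0:2, function(j) as.integer(y > j))
  expect_equal(unname(enc), unname(oracle))
  expect_error(encode_levels(c(0, 4), 4), "out of range")
  expect_error(encode_levels(c(0, -1), 4), "out of range")
})

test_that("ordinal loss has its closed forms and monotonicity", {
  # zero logits: (J-1) * ln 2 per sample, any label
  for (y in 0:3)
    expect_equal(donn_loss(0, c(0, 0, 0), y), 3 * log(2), tolerance = 1e-12)
  expect_equal(donn_loss(rep(0, 5), c(0, 0, 0), c(0, 1, 2, 3, 1)),
               15 * log(2), tolerance = 1e-12)
  # J = 2 reduces to binary cross-entropy (hand-written two-term formula)
  set.seed(5)
  s <- rnorm(5); a <- 0.3; y <- rbinom(5, 1, 0.5)
  p <- plogis(s + a)
  expect_equal(donn_loss(s, a, y),
               -sum(y * log(p) + (1 - y) * log(1 - p)), tolerance = 1e-10)
  # raising the score of a top-category sample lowers the loss
  l1 <- donn_loss(0.5, c(1, 0, -1), 3)
  l2 <- donn_loss(1.5, c(1, 0, -1), 3)
  expect_lt(l2, l1)
  # numerically stable far into the tails, never NaN
  expect_true(is.finite(donn_loss(c(-50, 50), c(1, 0, -1), c(0, 3))))
  expect_gte(donn_loss(c(-50, 50), c(1, 0, -1), c(0, 3)), 0)
  expect_error(donn_loss(c(0, NaN), c(1, 0, -1), c(0, 1)), "finite")
})

test_that("training makes progress and intercepts come out ordered", {
  coh <- small_cohort(2000, seed = 2,
                      alpha_true = c(2, 0, -2),
                      beta_oxi_true = c(1.5, -1, 1, 0.8, -0.6))
  m <- donn(coh$X_oxi, coh$y, epochs = 25, seed = 1)
  init_loss <- 3 * log(2) * 2000 * 0.9   # near-zero logits at init, train split
  expect_lt(m$train_log$train_loss[nrow(m$train_log)], init_loss)
  expect_true(m$alpha_ordered)
  expect_true(all(diff(m$params$alpha) < 0))
})

test_that("fits are reproducible for a fixed seed", {
  coh <- small_cohort(800, seed = 4)
  m1 <- donn(coh$X_oxi, coh$y, epochs = 8, seed = 42)
  m2 <- donn(coh$X_oxi, coh$y, epochs = 8, seed = 42)
  expect_identical(m1$train_log, m2$train_log)
  expect_identical(m1$params, m2$params)
  m3 <- donn(coh$X_oxi, coh$y, epochs = 8, seed = 43)
  expect_false(identical(m1$params, m3$params))
})

test_that("predictions are monotone across thresholds and batch-invariant", {
  coh <- small_cohort(800, seed = 6)
  m <- donn(coh$X_oxi, coh$y, epochs = 10, seed = 2)
  cum <- predict(m, coh$X_oxi, type = "cumulative")
  expect_true(all(cum > 0 & cum < 1))
  if (m$alpha_ordered)
    expect_true(all(cum[, 1] >= cum[, 2] & cum[, 2] >= cum[, 3]))
  s_all <- health_score(m, coh$X_oxi)
  s_rows <- vapply(seq_len(50), function(i)
    health_score(m, coh$X_oxi[i, , drop = FALSE]), numeric(1))
  expect_equal(s_rows, s_all[1:50], tolerance = 1e-12)
  probs <- predict(m, coh$X_oxi, type = "prob")
  expect_equal(unname(rowSums(probs)), rep(1, 800), tolerance = 1e-10)
})

test_that("zero coefficients give constant scores and sigma(alpha) rows", {
  coh <- small_cohort(500, seed = 8)
  m <- donn(coh$X_oxi, coh$y, epochs = 3, seed = 1)
  m$params$beta[] <- 0
  expect_equal(health_score(m, coh$X_oxi), rep(0, 500))
  cum <- predict(m, coh$X_oxi, type = "cumulative")
  for (j in 1:3)
    expect_equal(unname(cum[, j]), rep(plogis(m$params$alpha[j]), 500))
})

test_that("fit preconditions are enforced", {
  coh <- small_cohort(500, seed = 9)
  expect_error(donn(coh$X_oxi, coh$y, batch_size = 1000), "batch_size")
  y_degenerate <- rep(c(0L, 1L), 250)
  expect_error(donn(coh$X_oxi, y_degenerate, J = 4), "absent")
  m <- donn(coh$X_oxi, coh$y, epochs = 3, seed = 1)
  expect_error(predict(m, coh$X_meta), "columns")
  expect_error(health_score(m, coh$X_oxi[, 1:2]), "columns")
})

test_that("binary collapse modes relabel exactly as defined", {
  y <- c(0L, 1L, 2L, 3L)
  cl <- healthspace:::collapse_labels(y, "zero_vs_three", 4L)
  expect_identical(cl$keep, c(1L, 4L))       # rows with 1 or 2 discarded
  expect_identical(cl$y, c(0L, 1L))
  expect_identical(healthspace:::collapse_labels(y, "zero_vs_rest", 4L)$y,
                   c(0L, 1L, 1L, 1L))
  expect_identical(healthspace:::collapse_labels(y, "low_vs_high", 4L)$y,
                   c(0L, 0L, 1L, 1L))
  expect_identical(healthspace:::collapse_labels(y, "rest_vs_three", 4L)$y,
                   c(0L, 0L, 0L, 1L))
  coh <- small_cohort(600, seed = 10)
  expect_error(binary_dnn(coh$X_oxi, rep(1L, 600), mode = "low_vs_high"),
               "low_vs_high")
})

test_that("binary variants share the DONN loss for J = 2 parameters", {
  # with one threshold the ordinal loss is the binary cross-entropy, so all
  # collapse variants optimize the same objective given identical parameters
  set.seed(11)
  s <- rnorm(20); a <- 0.4; y <- rbinom(20, 1, 0.5)
  expect_equal(donn_loss(s, a, y),
               sum(healthspace:::bce_with_logits(s + a, y)),
               tolerance = 1e-12)
})

test_that("binary fit drops middle categories in zero_vs_three mode", {
  coh <- small_cohort(1500, seed = 12)
  m <- binary_dnn(coh$X_oxi, coh$y, mode = "zero_vs_three",
                  epochs = 8, seed = 1)
  expect_identical(m$n_used, sum(coh$y %in% c(0L, 3L)))
  expect_identical(m$J, 2L)
  m2 <- binary_dnn(coh$X_oxi, coh$y, mode = "low_vs_high",
                   epochs = 8, seed = 1)
  expect_identical(m2$n_used, 1500L)
})
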