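test_that("Wilson lower bound matches the quadratic-root form", {
  # independent oracle: the bound is the lower root of
  # (p_hat - p)^2 = z^2 p (1 - p) / n
  wilson_root <- function(p_hat, n, z = qnorm(0.975)) {
    (2 * n * p_hat + z^2 -
       z * sqrt(z^2 + 4 * n * p_hat * (1 - p_hat))) / (2 * (n + z^2))
  }
  set.seed(801)
  for (rep in 1:1000) {
    p <- runif(1)
    n <- sample(1:2000, 1)
    expect_equal(wilson_lower_bound(p, n), wilson_root(p, n),
                 tolerance = 1e-12)
  }
  expect_lt(wilson_lower_bound(0.5, 120), 0.5)
  expect_equal(wilson_lower_bound(1, 1e8), 1, tolerance = 1e-3)
  b <- wilson_lower_bound(0.5895, 120)
  expect_gt(b, 0.5)
  expect_lt(b, 0.505)
  expect_error(wilson_lower_bound(0.5, 0), "n must")
})

test_that("minimum significant accuracy sits exactly on the grid boundary", {
  for (n in c(48, 120, 300)) {
    thr <- min_significant_accuracy(n)
    expect_gt(wilson_lower_bound(thr / 100, n), 0.5)
    expect_lte(wilson_lower_bound((thr - 0.01) / 100, n), 0.5)
  }
  # strictly decreasing with n
  expect_gt(min_significant_accuracy(48), min_significant_accuracy(120))
  expect_gt(min_significant_accuracy(120), min_significant_accuracy(1000))
})

test_that("accuracy and confusion matrices are consistent", {
  y <- c("fear", "fear", "non-fear", "non-fear")
  ac <- accuracy_and_confusion(y, y)
  expect_equal(ac$accuracy, 1)
  expect_equal(unname(ac$normalized), diag(2))
  flip <- ifelse(y == "fear", "non-fear", "fear")
  expect_equal(accuracy_and_confusion(flip, y)$accuracy, 0)
  set.seed(802)
  p <- sample(c("fear", "non-fear"), 40, replace = TRUE)
  t <- sample(c("fear", "non-fear"), 40, replace = TRUE)
  ac <- accuracy_and_confusion(p, t)
  expect_equal(ac$accuracy, sum(diag(ac$counts)) / sum(ac$counts))
  expect_equal(unname(rowSums(ac$normalized)), c(1, 1))
  expect_error(accuracy_and_confusion(character(0), character(0)), "empty")
})

test_that("occlusion importance is normalized, symmetric and degenerate-safe", {
  # when masking changes nothing (inputs already at the mask value) the
  # normalization is degenerate: uniform importances with a warning
  m <- pqc_model("qcnn", "k1", "c_head", n_channels = 3)
  set.seed(804)
  dead <- list(model = m, weights = init_weights(m))
  x <- array(0, c(6, 3, 10))
  expect_warning(imp <- occlusion_importance(dead, x), "insensitive")
  expect_equal(unname(imp), rep(1 / 3, 3))

  # two channels with identical data and identical kernel weights, fused by
  # averaging, must come out equally important
  m2 <- pqc_model("qcnn", "k1", "avg", n_channels = 2)
  set.seed(803)
  kw <- runif(8, -0.5, 0.5)
  w2 <- rep(rep(kw, 2), 4)  # same weights for both channels in every layer
  x2 <- array(runif(5 * 2 * 10, -1, 1), c(5, 2, 10))
  x2[, 2, ] <- x2[, 1, ]
  imp2 <- occlusion_importance(list(model = m2, weights = w2), x2)
  expect_equal(sum(imp2), 1)
  expect_equal(unname(imp2[1]), unname(imp2[2]), tolerance = 1e-12)
})

test_that("accuracy aggregation mirrors the per-subject table layout", {
  res <- data.frame(fold = rep(c("S1", "S2", "S3"), each = 2),
                    val_acc = c(0.8, 0.9, 0.7, 0.7, 0.6, 0.8))
  tab <- aggregate_accuracy(res)
  expect_equal(nrow(tab), 4L)  # subjects + Mean row
  expect_equal(tab$subject[4], "Mean")
  expect_equal(tab$mean_acc[1], 85)
  expect_equal(tab$sd_acc[2], 0)
  expect_equal(tab$mean_acc[4], mean(tab$mean_acc[1:3]))
  one <- aggregate_accuracy(data.frame(fold = "S1", val_acc = 0.75))
  expect_equal(one$sd_acc, c(0, 0))
})
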