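test_that("LOSO folds have the protocol's sizes and partition the windows", {
  ts <- simulate_dataset(synth_config(n_subjects = 14, seed = 701))
  ws <- make_windows(extract_analysis_window(ts))
  plan <- loso_splits(ws)
  expect_equal(plan$mode, "subject_independent")
  expect_length(plan$folds, 14L)
  for (f in plan$folds) {
    expect_length(f$train, 1560L)
    expect_length(f$val, 120L)
    expect_length(intersect(f$train, f$val), 0L)
  }
  all_val <- sort(unlist(lapply(plan$folds, `[[`, "val")))
  expect_equal(all_val, seq_len(dim(ws$x)[1]))
  tiny <- subset_windows(ws, which(ws$meta$subject == "S1"))
  expect_error(loso_splits(tiny), "at least 2")
})

test_that("subject-dependent folds use the first six trials (3/3)", {
  ts <- simulate_dataset(synth_config(n_subjects = 3, seed = 702))
  ws <- make_windows(extract_analysis_window(ts))
  plan <- subject_dependent_splits(ws)
  expect_equal(plan$mode, "subject_dependent")
  for (f in plan$folds) {
    expect_length(f$train, 72L)
    expect_length(f$val, 48L)
    expect_length(intersect(f$train, f$val), 0L)
    tr_lab <- table(ws$meta$label[f$train]) / 12
    expect_equal(unname(tr_lab[c("fear", "non-fear")]), c(3, 3),
                 ignore_attr = TRUE)
    va_lab <- table(ws$meta$label[f$val]) / 12
    expect_equal(unname(va_lab[c("fear", "non-fear")]), c(2, 2),
                 ignore_attr = TRUE)
    expect_length(intersect(unique(ws$meta$trial[f$train]),
                            unique(ws$meta$trial[f$val])), 0L)
  }
  # an ordering that cannot give 3/3 in the first six trials is a data error
  bad <- ts
  bad$labels[1, ] <- rep(c("fear", "non-fear"), each = 5)
  wsb <- make_windows(extract_analysis_window(bad))
  expect_error(subject_dependent_splits(wsb), "3/3")
})

test_that("early stopping is gated on training accuracy", {
  h <- function(acc, loss) data.frame(train_acc = acc, val_loss = loss)
  # 5 non-improving epochs but accuracy below the gate: keep training
  expect_false(should_stop(h(rep(0.70, 6), c(1, rep(1.1, 5)))))
  # same loss curve with the gate reached: stop
  expect_true(should_stop(h(c(rep(0.70, 5), 0.80), c(1, rep(1.1, 5)))))
  # improvement at epoch 4 resets the patience counter
  expect_false(should_stop(h(rep(0.9, 5), c(1, 1.1, 1.2, 0.9, 1.05))))
  # never stops before patience epochs have elapsed past the best
  expect_false(should_stop(h(rep(0.9, 5), c(1, 1.1, 1.2, 1.3, 1.4))))
  expect_true(should_stop(h(rep(0.9, 6), c(1, 1.1, 1.2, 1.3, 1.4, 1.5))))
})

test_that("training is deterministic given (seed, data, config)", {
  set.seed(703)
  m <- pqc_model("qcnn", "k1", "avg", n_channels = 2)
  x <- array(runif(8 * 2 * 10, -1, 1), c(8, 2, 10))
  y <- rep(c(0L, 1L), 4)
  cfg <- train_config("sd", max_epochs = 4)
  f1 <- pqc_fit(m, x, y, x, y, cfg, seed = 5)
  f2 <- pqc_fit(m, x, y, x, y, cfg, seed = 5)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
  f3 <- pqc_fit(m, x, y, x, y, cfg, seed = 6)
  expect_false(identical(f1$weights, f3$weights))
})

test_that("a zero learning rate leaves the weights unchanged", {
  m <- pqc_model("qcnn", "k1", "avg", n_channels = 2)
  x <- array(runif(4 * 2 * 10, -1, 1), c(4, 2, 10))
  y <- c(0L, 1L, 0L, 1L)
  w0 <- init_weights(m, 7)
  fit <- pqc_fit(m, x, y, config = train_config("si", lr = 0,
                                                max_epochs = 3),
                 seed = 7)
  expect_equal(fit$weights, w0, tolerance = 1e-15)
  expect_equal(fit$history$train_loss, rep(fit$history$train_loss[1], 3))
})

test_that("training loss decreases on separable toy data", {
  m <- pqc_model("qcnn", "k1", "c_head", n_channels = 2)
  x <- array(0, c(2, 2, 10))
  x[1, , ] <- -1
  x[2, , ] <- 1
  y <- c(0L, 1L)
  fit <- pqc_fit(m, x, y, config = train_config("sd", lr = 0.005,
                                                max_epochs = 20),
                 seed = 1)
  expect_true(all(diff(fit$history$train_loss) <= 1e-8))
})

test_that("run_repeats records distinct seeds and exact summaries", {
  m <- pqc_model("qcnn", "k1", "avg", n_channels = 2)
  x <- array(runif(8 * 2 * 10, -1, 1), c(8, 2, 10))
  y <- rep(c(0L, 1L), 4)
  cfg <- train_config("sd", max_epochs = 3)
  rr <- run_repeats(m, x, y, x, y, cfg, seeds = 0:2)
  expect_length(rr$fits, 3L)
  expect_equal(vapply(rr$fits, `[[`, numeric(1), "seed"), c(0, 1, 2))
  expect_equal(rr$mean, mean(rr$summary$val_acc))
  # degenerate: identical seeds give zero spread
  rr0 <- run_repeats(m, x, y, x, y, cfg, seeds = c(4, 4))
  expect_equal(rr0$sd, 0)
})

test_that("fit object methods expose weights, predictions and curves", {
  set.seed(704)
  m <- pqc_model("qcnn", "k1", "avg", n_channels = 2)
  x <- array(runif(8 * 2 * 10, -1, 1), c(8, 2, 10))
  y <- rep(c("fear", "non-fear"), 4)
  fit <- pqc_fit(m, x, y, x, y, train_config("sd", max_epochs = 3),
                 seed = 2)
  expect_length(coef(fit), count_params(m))
  pred <- predict(fit, x)
  expect_true(all(pred %in% c("fear", "non-fear")))
  sc <- predict(fit, x, type = "score")
  expect_equal(dim(sc), c(8L, 2L))
  expect_true(all(abs(sc) <= 1))
  pr <- predict(fit, x, type = "prob")
  expect_equal(rowSums(pr), rep(1, 8))
  expect_output(print(fit), "pqc_fit")
  expect_output(summary(fit), "trainable parameters")
})
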