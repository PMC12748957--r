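test_that("parameter accounting matches the architecture definitions", {
  expect_equal(count_params(build_aepqc()), 112L)
  expect_equal(count_params(pqc_model("qcnn", "k1", "c_head")),
               4L * 27L * 8L + 18L)
  expect_equal(count_params(pqc_model("qcnn", "k2", "avg")),
               4L * 27L * 39L)
  # per-kernel weights: K1 = 2 per wire, K2 = 9 U3 params/wire + 3 entanglers
  expect_equal(attr(qfnirs:::.kernel_program("k1"), "n_params"), 8L)
  expect_equal(attr(qfnirs:::.kernel_program("k2"), "n_params"), 39L)
  expect_equal(attr(qfnirs:::.chead_program(), "n_params"), 18L)
  # every trainable parameter addressable exactly once
  for (m in list(build_aepqc(), pqc_model("qcnn", "k1", "c_head"))) {
    map <- weight_index_map(m)
    expect_equal(nrow(map), count_params(m))
    expect_equal(sort(map$pos), seq_len(count_params(m)))
  }
})

test_that("AEPQC forward is deterministic, bounded and shape-checked", {
  m <- build_aepqc()
  x <- runif(250, -1, 1)
  w0 <- rep(0, 112)
  s0 <- aepqc_forward(x, w0)
  expect_true(all(is.finite(s0)))
  set.seed(501)
  w <- init_weights(m)
  s1 <- aepqc_forward(x, w)
  expect_identical(s1, aepqc_forward(x, w))
  expect_true(all(abs(s1) <= 1))
  expect_error(aepqc_forward(runif(270), w), "length 250")
})

test_that("kernel forward honours its contracts", {
  expect_equal(kernel_forward(rep(0, 4), rep(0, 8), "k1"), c(1, 1))
  expect_equal(kernel_forward(rep(0, 4), rep(0, 39), "k2"), c(1, 1))
  set.seed(502)
  f <- runif(4, 0, pi)
  expect_true(all(abs(kernel_forward(f, runif(8, -1, 1), "k1")) <= 1))
  expect_true(all(abs(kernel_forward(f, runif(39, -1, 1), "k2")) <= 1))
  expect_error(kernel_forward(c(-1, 0, 0, 0), rep(0, 8), "k1"),
               "\\[0, pi\\]")
  expect_error(kernel_forward(rep(0, 4), rep(0, 7), "k1"), "8 weights")
})

test_that("classification head composes embedding, rotations and the ring", {
  set.seed(503)
  h <- runif(54, -1, 1)
  # zero rotations reduce the head to the CNOT ring on the embedded state
  out <- c_head_forward(h, rep(0, 18))
  st <- amplitude_embed(h, 6)
  for (i in 0:5)
    st <- apply_gate(st, gate_spec("CNOT", c(i, (i + 1) %% 6)))
  expect_equal(out, c(expect_z(st, 0), expect_z(st, 1)), tolerance = 1e-12)
  # full compositional oracle at random weights
  w <- runif(18, -1, 1)
  st2 <- amplitude_embed(h, 6)
  for (i in 0:5) st2 <- apply_gate(st2, gate_spec("RY", i, w[i + 1]))
  for (i in 0:5) st2 <- apply_gate(st2, gate_spec("RZ", i, w[6 + i + 1]))
  for (i in 0:5) st2 <- apply_gate(st2, gate_spec("RX", i, w[12 + i + 1]))
  for (i in 0:5)
    st2 <- apply_gate(st2, gate_spec("CNOT", c(i, (i + 1) %% 6)))
  expect_equal(c_head_forward(h, w),
               c(expect_z(st2, 0), expect_z(st2, 1)), tolerance = 1e-12)
  expect_error(c_head_forward(runif(10), rep(0, 18)), "54")
})

test_that("QCNN temporal chain contracts 10 -> 8 -> 6 -> 4 -> 2", {
  expect_equal(qfnirs:::.qcnn_layer_sizes(10L), c(10L, 8L, 6L, 4L, 2L))
  expect_equal(qfnirs:::.qcnn_layer_sizes(8L, n_layers = 1L)[2], 6L)
})

test_that("QCNN forward equals a hand-composed chain of core operations", {
  set.seed(504)
  model <- pqc_model("qcnn", "k1", "avg", n_channels = 2)
  w <- init_weights(model)
  x <- matrix(runif(20, 0, pi), 2, 10)
  got <- qcnn_forward(x, w, "k1", "avg")

  # manual composition per channel using only kernel_forward + fuse
  P <- 8L
  kw <- function(l, ch) w[((l - 1) * 2 + (ch - 1)) * P + seq_len(P)]
  cs <- t(vapply(1:2, function(ch) {
    v <- x[ch, ]
    for (l in 1:4) {
      K <- (length(v) - 4) / 2 + 1
      out <- unlist(lapply(seq_len(K), function(k)
        kernel_forward(v[(2 * k - 1):(2 * k + 2)], kw(l, ch), "k1")))
      v <- if (l < 4) (out + 1) * pi / 2 else out
    }
    v
  }, numeric(2)))
  expect_equal(got$channel_scores, cs, tolerance = 1e-12)
  expect_equal(got$scores, fuse(cs, "avg"), tolerance = 1e-12)
})

test_that("fusion is a pure column-wise reduction", {
  cs <- cbind(c(0.2, -0.9, 0.5), c(0.1, 0.2, 0.3))
  expect_equal(fuse(cs, "amax"), c(-0.9, 0.3))
  expect_equal(fuse(cs, "max"), c(0.5, 0.3))
  same <- matrix(rep(c(0.4, -0.2), each = 5), 5, 2)
  expect_equal(fuse(same, "avg"), c(0.4, -0.2))
  set.seed(505)
  m <- matrix(runif(54, -1, 1), 27, 2)
  expect_true(all(fuse(m, "max") >= fuse(m, "avg")))
  perm <- sample(27)
  for (mode in c("avg", "max", "amax"))
    expect_equal(fuse(m[perm, ], mode), fuse(m, mode))
  expect_error(fuse(m[0, , drop = FALSE], "avg"), "no channel")
  expect_error(fuse(matrix(c(1, NA), 1, 2), "avg"), "finite")
})

test_that("changing the fusion mode leaves channel scores bit-identical", {
  set.seed(506)
  w <- init_weights(pqc_model("qcnn", "k1", "avg", n_channels = 3))
  x <- matrix(runif(30, 0, pi), 3, 10)
  outs <- lapply(c("avg", "max", "amax"), function(fu)
    qcnn_forward(x, w, "k1", fu))
  expect_identical(outs[[1]]$channel_scores, outs[[2]]$channel_scores)
  expect_identical(outs[[1]]$channel_scores, outs[[3]]$channel_scores)
})

test_that("model archives round-trip through plain text", {
  set.seed(507)
  m <- pqc_model("qcnn", "k2", "c_head")
  w <- init_weights(m)
  path <- tempfile(fileext = ".txt")
  write_pqc_model(m, w, path)
  back <- read_pqc_model(path)
  expect_identical(back$model$family, m$family)
  expect_identical(back$model$kernel, m$kernel)
  expect_identical(back$model$fusion, m$fusion)
  expect_equal(back$weights, w, tolerance = 1e-15)
})
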