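# helper: wrap a plain (windows x channels x samples) array as a window_set
ws_from_array <- function(x, labels = NULL) {
  n <- dim(x)[1]
  structure(list(
    x = x,
    meta = data.frame(subject = "S1", trial = 1L, window = seq_len(n),
                      label = labels %||% rep(c("fear", "non-fear"),
                                              length.out = n)),
    channels = seq_len(dim(x)[2]), sampling_rate = 10),
    class = "window_set")
}

test_that("the analysis window keeps samples [3 s, 15 s) and guards length", {
  # signal value = 0-based sample index, one subject/trial/channel
  sig <- array(0, c(1, 2, 1, 300))
  sig[1, 1, 1, ] <- 0:299
  sig[1, 2, 1, ] <- 0:299
  ts <- trial_set(sig, matrix(c("fear", "non-fear"), 1, 2))
  out <- extract_analysis_window(ts)
  expect_equal(dim(out$signals)[4], 120L)
  expect_equal(out$signals[1, 1, 1, 1], 30)    # 3.0 s included
  expect_equal(out$signals[1, 1, 1, 120], 149) # 15.0 s excluded
  # a second application (trial now 12 s long) is a data error
  expect_error(extract_analysis_window(out), "at least 150")
})

test_that("windows tile each trial exactly, 12 per trial", {
  set.seed(601)
  ts <- simulate_dataset(synth_config(n_subjects = 2, n_channels = 4,
                                      informative_channels = 2L,
                                      seed = 601))
  aw <- extract_analysis_window(ts)
  ws <- make_windows(aw)
  expect_equal(dim(ws$x), c(2 * 10 * 12, 4, 10))
  expect_equal(max(ws$meta$window), 12L)
  # concatenating a trial's windows reconstructs the trial
  sel <- ws$meta$subject == "S1" & ws$meta$trial == 3
  rebuilt <- do.call(cbind, lapply(which(sel), function(i) ws$x[i, , ]))
  expect_identical(rebuilt, aw$signals[1, 3, , ])
  # labels propagate from the trial
  expect_equal(unique(ws$meta$label[sel]), ts$labels[1, 3])
  # length not divisible by the window is an error
  short <- aw
  short$signals <- short$signals[, , , 1:115, drop = FALSE]
  expect_error(make_windows(short), "divisible")
})

test_that("robust scaler quartiles follow the type-7 rule per channel", {
  x <- array(0, c(5, 2, 1))
  x[, 1, 1] <- 0:4
  x[, 2, 1] <- c(10, 20, 30, 40, 50)
  sc <- fit_robust_scaler(ws_from_array(x))
  expect_equal(sc$q1, c(1, 20))
  expect_equal(sc$q2, c(2, 30))
  expect_equal(sc$q3, c(3, 40))
  # degenerate channel is a named error
  x[, 2, 1] <- 7
  expect_error(fit_robust_scaler(ws_from_array(x)), "2")
})

test_that("the arctangent transform is exact, bounded and monotone", {
  sc <- structure(data.frame(channel = 1L, q1 = 0, q2 = 1, q3 = 2),
                  class = c("robust_scaler", "data.frame"))
  expect_equal(apply_robust_arctan(1, sc), 0)
  expect_equal(apply_robust_arctan(3, sc), pi / 4)
  big <- apply_robust_arctan(c(-1e12, 1e12), sc)
  expect_true(all(big > -pi / 2 & big < pi / 2))
  v <- sort(rnorm(50))
  expect_true(all(diff(apply_robust_arctan(v, sc)) > 0))
})

test_that("the embedding-range map is the pi/2 shift and rejects bad input", {
  expect_equal(rescale_to_embedding_range(0), pi / 2)
  eps <- 1e-9
  expect_equal(rescale_to_embedding_range(-pi / 2 + eps), eps)
  v <- sort(runif(20, -1.5, 1.5))
  expect_true(all(diff(rescale_to_embedding_range(v)) > 0))
  expect_error(rescale_to_embedding_range(2), "pi/2")
})

test_that("a single extreme outlier barely moves other scaled values", {
  set.seed(602)
  n <- 120
  x <- array(rnorm(n * 1 * 10), c(n, 1, 10))
  ws <- ws_from_array(x)
  base <- apply_robust_arctan(ws, fit_robust_scaler(ws))
  ws2 <- ws
  ws2$x[1, 1, 1] <- 1e6
  pert <- apply_robust_arctan(ws2, fit_robust_scaler(ws2))
  expect_lt(max(abs(base$x[-1, 1, ] - pert$x[-1, 1, ])), 0.05)
})

test_that("Pearson pruning drops the uninformative channels", {
  ts <- simulate_dataset(synth_config(
    n_subjects = 4, n_channels = 10,
    informative_channels = setdiff(1:10, c(5L, 9L)),
    effect_amplitude = 2, noise_sd = 0.3, outlier_rate = 0, seed = 603))
  ws <- make_windows(extract_analysis_window(ts))
  sel <- select_channels_pearson(ws, n_drop = 2)
  expect_equal(sel$drop, c(5L, 9L))
  expect_equal(sel$keep, setdiff(1:10, c(5L, 9L)))
  # n_drop = 0 keeps everything
  expect_equal(select_channels_pearson(ws, n_drop = 0)$keep, 1:10)
  # a constant channel scores 0 rather than erroring
  ws$x[, 3, ] <- 1
  expect_equal(unname(select_channels_pearson(ws, 2)$scores[3]), 0)
})

test_that("flattening is channel-major and invertible", {
  w <- matrix(seq_len(250), 25, 10)
  v <- flatten_for_aepqc(w)
  expect_length(v, 250)
  expect_equal(v[1:10], w[1, ])   # channel 1's samples first
  expect_equal(unflatten_window(v, 25), w)
  expect_length(flatten_for_aepqc(matrix(0, 27, 10)), 270)
  expect_error(flatten_for_aepqc(matrix(0, 25, 9)), "10 samples")
})

test_that("validation data is scaled with training parameters, not refit", {
  set.seed(604)
  tr <- ws_from_array(array(rnorm(40 * 2 * 10), c(40, 2, 10)))
  va <- ws_from_array(array(rnorm(10 * 2 * 10, mean = 5), c(10, 2, 10)))
  sc <- fit_robust_scaler(tr)
  out <- apply_robust_arctan(va, sc)
  manual <- atan((va$x[3, 2, ] - sc$q2[2]) / (sc$q3[2] - sc$q1[2]))
  expect_equal(out$x[3, 2, ], manual)
})
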