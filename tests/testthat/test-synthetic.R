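test_that("the HRF kernel has the canonical double-gamma shape", {
  h <- hrf_kernel()
  expect_length(h, 300L)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  pk <- hrf_params()
  peak_idx <- (pk$onset_delay + pk$peak_time) * 10 + 1
  expect_lte(abs(which.max(h) - peak_idx), 1)
  expect_gt(sum(h), 0)
  # undershoot dips below zero after the positive lobe
  expect_lt(min(h), 0)
})

test_that("simulation is deterministic under the seed and shape-correct", {
  cfg <- synth_config(n_subjects = 3, seed = 901)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$signals, b$signals)
  expect_identical(a$labels, b$labels)
  expect_equal(dim(a$signals), c(3L, 10L, 27L, 300L))
  expect_true(all(rowSums(a$labels == "fear") == 5))
  d <- simulate_dataset(synth_config(n_subjects = 3, seed = 902))
  expect_false(identical(a$signals, d$signals))
  expect_error(synth_config(outlier_rate = 2), "outlier_rate")
  expect_error(synth_config(informative_channels = 99), "subset")
  expect_error(synth_config(n_trials = 7), "even")
})

test_that("label correlation reflects the injected effect", {
  # zero effect: every channel's label correlation is near zero
  ts0 <- simulate_dataset(synth_config(effect_amplitude = 0, seed = 903))
  ws0 <- make_windows(extract_analysis_window(ts0))
  expect_equal(dim(ws0$x)[1], 1680L)
  y <- as.numeric(ws0$meta$label == "fear")
  r0 <- vapply(1:27, function(ch)
    abs(cor(rowMeans(ws0$x[, ch, ]), y)), numeric(1))
  expect_lt(max(r0), 0.1)

  # strong effect: informative channels dominate
  inf <- c(8L, 9L, 10L)
  ts1 <- simulate_dataset(synth_config(effect_amplitude = 2,
                                       noise_sd = 0.3, seed = 904))
  ws1 <- make_windows(extract_analysis_window(ts1))
  y1 <- as.numeric(ws1$meta$label == "fear")
  r1 <- vapply(1:27, function(ch)
    abs(cor(rowMeans(ws1$x[, ch, ]), y1)), numeric(1))
  expect_gt(min(r1[inf]), max(r1[-inf]))
})

test_that("datasets round-trip through the plain-text layout", {
  ts <- simulate_dataset(synth_config(n_subjects = 2, n_trials = 4,
                                      seed = 905))
  dir <- tempfile("ds")
  write_dataset(ts, dir)
  back <- read_dataset(dir)
  expect_identical(back$labels, ts$labels)
  expect_identical(back$subject_ids, ts$subject_ids)
  expect_equal(back$sampling_rate, ts$sampling_rate)
  expect_true(back$synthetic)
  expect_lt(max(abs(back$signals - ts$signals)), 1e-12)

  # tampered manifest: subject file with wrong channel count
  man <- readLines(file.path(dir, "manifest.tsv"))
  writeLines(sub("# n_channels 27", "# n_channels 26", man),
             file.path(dir, "manifest.tsv"))
  expect_error(read_dataset(dir), "channel")
  writeLines(man, file.path(dir, "manifest.tsv"))
  # drop one subject's rows: trial counts become inconsistent
  keep <- !grepl("^S2\t", man) | !grepl("\t4\t", man)
  writeLines(man[keep], file.path(dir, "manifest.tsv"))
  expect_error(read_dataset(dir), "inconsistent|balanced|unbalanced")
})

test_that("the micro fixture runs the preprocessing stack end to end", {
  fx <- toy_fixtures()
  ws <- make_windows(extract_analysis_window(fx$micro_dataset))
  expect_equal(dim(ws$x)[1], 96L)  # 2 subjects x 4 trials x 12 windows
  sc <- apply_robust_arctan(ws, fit_robust_scaler(ws))
  expect_true(all(sc$x > -pi / 2 & sc$x < pi / 2))
  emb <- rescale_to_embedding_range(sc)
  expect_true(all(emb$x > 0 & emb$x < pi))
})
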