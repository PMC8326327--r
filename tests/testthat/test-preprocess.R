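test_that("resampling preserves duration, passband sines, and kills aliases", {
  eeg <- sine_eeg(c(5, 300), 2048, duration = 10)
  out <- resample(eeg, 512)
  expect_equal(ncol(out$data), 5120)
  expect_equal(out$sfreq, 512)
  # 5 Hz sine survives with < 2% amplitude error (ignore filter edges)
  mid <- 512:4608
  expect_equal(max(abs(out$data[1, mid])), 1, tolerance = 0.02)
  # 300 Hz component attenuated by > 95%
  expect_lt(max(abs(out$data[2, mid])), 0.05)
  expect_error(resample(out, 2048), "must not exceed")
})

test_that("common average reference zeroes the channel mean and is idempotent", {
  eeg <- generate_background(8, 256, 2, noise_scale = 5, seed = 4)
  out <- common_average_reference(eeg)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  # identical constant on all channels vanishes
  const <- eeg_record(matrix(3.7, 4, 100), 100, paste0("c", 1:4))
  expect_true(all(abs(common_average_reference(const)$data) < 1e-12))
  # idempotence
  twice <- common_average_reference(out)
  expect_equal(twice$data, out$data, tolerance = 1e-12)
  one_ch <- eeg_record(matrix(0, 1, 10), 10, "a")
  expect_error(common_average_reference(one_ch), "at least 2")
})

test_that("band-pass keeps the passband, rejects 50 Hz and DC", {
  eeg <- sine_eeg(c(5, 50), 512, duration = 8)
  eeg$data <- eeg$data + 2  # DC offset
  out <- bandpass(eeg)
  mid <- 1024:3072
  expect_equal(max(abs(out$data[1, mid])), 1, tolerance = 0.05)
  expect_lt(max(abs(out$data[2, mid])), 0.1)
  expect_lt(abs(mean(out$data[1, mid])), 0.01)  # DC gone (filter edges aside)
  expect_error(bandpass(eeg, 10, 5), "low < high")
})

test_that("epoch extraction matches the schedule's bookkeeping", {
  ep <- train_epochs_default()
  expect_equal(dim(ep$data)[1], 1080)
  expect_equal(sum(ep$info$label), 180)
  expect_equal(dim(ep$data)[3], 204)  # floor(0.4 * 512)

  # empty schedule gives an empty epoch set
  eeg <- generate_background(2, 256, 2, noise_scale = 0)
  empty <- tibble::tibble(onset_s = numeric(0), stimulus_id = integer(0),
                          block_id = integer(0), is_target = logical(0))
  ep0 <- extract_epochs(eeg, empty)
  expect_equal(dim(ep0$data)[1], 0)

  # out-of-bounds event named in the error
  bad <- tibble::tibble(onset_s = 1.9, stimulus_id = 0L, block_id = 1L,
                        is_target = FALSE)
  expect_error(extract_epochs(eeg, bad), "event 1")
})

test_that("baseline correction zeroes per-channel epoch means, idempotently", {
  data <- array(stats::rnorm(5 * 3 * 20), c(5, 3, 20)) + 4
  ep <- make_epochs(data, labels = rep(0, 5))
  out <- baseline_correct(ep)
  for (e in 1:5) expect_lt(max(abs(rowMeans(out$data[e, , ]))), 1e-12)
  again <- baseline_correct(out)
  expect_equal(again$data, out$data, tolerance = 1e-12)
  # constant epoch becomes all zeros
  cst <- make_epochs(array(7, c(1, 2, 10)), labels = 0)
  expect_true(all(baseline_correct(cst)$data == 0))
})

test_that("feature flattening is channel-major and round-trips", {
  ep <- train_epochs_default()
  fm <- to_features(ep)
  expect_equal(ncol(fm$values), 32 * 51)
  expect_equal(nrow(fm$feature_map), 32 * 51)
  # feature_map is a bijection onto the channel x time grid
  expect_equal(nrow(dplyr::distinct(fm$feature_map, channel, time_ms)),
               32 * 51)

  # 1 channel, 4 samples: features equal the samples in order
  tiny <- make_epochs(array(c(1, 2, 3, 4), c(1, 1, 4)), labels = 1,
                      window = c(0, 4000), sfreq = 1)
  fm1 <- to_features(tiny, feature_sfreq = 1)
  expect_equal(as.numeric(fm1$values), c(1, 2, 3, 4))

  # unflatten via the feature map recovers the decimated samples
  e <- 17
  ch <- "Pz"
  cols <- fm$feature_map$feature[fm$feature_map$channel == ch]
  grid_idx <- seq(1, by = 4, length.out = 51)
  expect_equal(as.numeric(fm$values[e, cols]),
               as.numeric(ep$data[e, match(ch, ep$channel_names), grid_idx]))
})

test_that("the full chain preserves counts and finds the injected feature", {
  tpl <- erp_template(latency_jitter_sd = 0, amplitude_jitter_sd = 0)
  sch <- build_stimulus_schedule(6, 5, 187.5, 0, seed = 2, t0_s = 1)
  eeg <- generate_background(32, 512, 9, noise_scale = 0)
  eeg <- inject_erp(eeg, sch, tpl)
  sess <- list(eeg = eeg, schedule = sch)
  ep <- preprocess_session(sess)
  expect_equal(dim(ep$data)[1], nrow(sch))
  expect_equal(ep$info$label, as.integer(sch$is_target))

  fm <- to_features(ep)
  mean_t <- colMeans(fm$values[fm$info$label == 1, , drop = FALSE])
  top <- fm$feature_map[which.max(mean_t), ]
  expect_equal(top$channel, "Oz")
  expect_lt(abs(top$time_ms - 350), 8)
})
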