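test_that("background noise has the requested shape and a 1/f spectrum", {
  z <- generate_background(4, 256, 2, noise_scale = 0)
  expect_equal(dim(z$data), c(4, 512))
  expect_true(all(z$data == 0))

  bg <- generate_background(32, 2048, 10, noise_scale = 10, seed = 5)
  expect_equal(dim(bg$data), c(32, 20480))
  expect_equal(unname(apply(bg$data, 1, stats::sd)), rep(10, 32),
               tolerance = 1e-6)

  # band power decreasing across octave bands spanning 1-40 Hz
  long <- generate_background(1, 256, 120, noise_scale = 1, seed = 9)
  x <- long$data[1, ]
  spec <- Mod(stats::fft(x))^2
  f <- (seq_along(spec) - 1) * 256 / length(spec)
  bandpow <- vapply(list(c(1, 2.5), c(2.5, 6.3), c(6.3, 16), c(16, 40)),
                    function(b) mean(spec[f >= b[1] & f < b[2]]), numeric(1))
  expect_true(all(diff(bandpow) < 0))
})

test_that("ERP injection places the template where and how large it says", {
  tpl <- erp_template(latency_jitter_sd = 0, amplitude_jitter_sd = 0)
  base <- generate_background(32, 512, 4, noise_scale = 0)
  sch <- tibble::tibble(onset_s = 1, stimulus_id = 0L, block_id = 1L,
                        is_target = TRUE)

  out <- inject_erp(base, sch, tpl)
  oz <- out$data[match("Oz", out$channel_names), ]
  expect_equal(max(oz), 5 * tpl$topography[["Oz"]], tolerance = 1e-4)
  expect_equal((which.max(oz) - 1) / 512, 1 + 0.350, tolerance = 1 / 512)
  # other channels scale by their topography weight
  fz <- out$data[match("Fz", out$channel_names), ]
  expect_equal(max(fz), 5 * tpl$topography[["Fz"]], tolerance = 1e-4)
  # input untouched; zero-amplitude template is a no-op
  expect_true(all(base$data == 0))
  tpl0 <- erp_template(peak_amplitude = 0)
  expect_identical(inject_erp(base, sch, tpl0)$data, base$data)

  # event too close to the recording end
  sch_bad <- tibble::tibble(onset_s = 3.8, stimulus_id = 0L, block_id = 1L,
                            is_target = TRUE)
  expect_error(inject_erp(base, sch_bad, tpl), "exceeds the recording")
})

test_that("averaged target-minus-nontarget epochs recover the template", {
  tpl <- erp_template()
  sch <- build_stimulus_schedule(6, 30, 187.5, target_id = 0, seed = 7,
                                 t0_s = 1)
  eeg <- generate_background(32, 512, 40, noise_scale = 1, seed = 7)
  eeg <- inject_erp(eeg, sch, tpl, seed = 8)
  ep <- extract_epochs(eeg, sch, window = c(0, 700))
  oz <- match("Oz", ep$channel_names)
  avg_t <- colMeans(ep$data[ep$info$label == 1, oz, ])
  avg_n <- colMeans(ep$data[ep$info$label == 0, oz, ])
  diffc <- avg_t - avg_n
  peak_ms <- (which.max(diffc) - 1) / 512 * 1000
  expect_lt(abs(peak_ms - 350), 20)
})

test_that("grand-average target amplitude is linear in peak amplitude", {
  amps <- c(2, 5, 8)
  peaks <- vapply(amps, function(a) {
    tpl <- erp_template(peak_amplitude = a, latency_jitter_sd = 0,
                        amplitude_jitter_sd = 0)
    sch <- build_stimulus_schedule(6, 10, 187.5, 0, seed = 1, t0_s = 1)
    eeg <- generate_background(32, 512, 16, noise_scale = 0)
    eeg <- inject_erp(eeg, sch, tpl)
    ep <- extract_epochs(eeg, sch, window = c(200, 600))
    max(colMeans(ep$data[ep$info$label == 1, match("Oz", ep$channel_names), ]))
  }, numeric(1))
  slope <- stats::coef(stats::lm(peaks ~ amps))[["amps"]]
  expect_equal(slope, 1, tolerance = 0.05)
})

test_that("simulated sessions have the protocol's event bookkeeping", {
  train <- train_session_default()
  expect_equal(sum(train$schedule$is_target), 180)
  expect_equal(sum(!train$schedule$is_target), 900)
  expect_equal(nrow(train$targets), 6)
  expect_equal(train$targets$target_id, 0:5)

  online <- simulate_session("online", noise_scale = 0, seed = 2)
  expect_equal(nrow(online$schedule), 12 * 120)
  expect_equal(sum(online$schedule$is_target), 12 * 20)
  expect_equal(nrow(online$targets), 12)
  expect_true(all(online$targets$step %in% 1:2))
  # each selection block: 120 events, 20 of them target
  per_block <- dplyr::count(online$schedule, block_id,
                            wt = as.integer(is_target))
  expect_true(all(per_block$n == 20))

  # bit-reproducibility under a fixed seed
  a <- simulate_session("online", seed = 77)
  b <- simulate_session("online", seed = 77)
  expect_identical(a$eeg$data, b$eeg$data)
  expect_identical(tibble::as_tibble(a$schedule), tibble::as_tibble(b$schedule))
  expect_identical(a$targets, b$targets)
})
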