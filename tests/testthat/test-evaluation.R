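test_that("the Wolpaw rate reproduces every checked published cell to 0.01", {
  cells <- tibble::tribble(
    ~acc, ~t_s, ~printed,
    # online table cells (accuracy printed as truncated percent), T = 30.5 s
    100, 30.5, 5.09,   66, 30.5, 1.71,   91, 30.5, 3.82,   83, 30.5, 3.01,
    # blink-count table, N = 1 (T = 6.62 s)
    49.16, 6.62, 3.66,  50, 6.62, 3.84,  42.50, 6.62, 2.41,
    66.25, 6.62, 7.97,  36.25, 6.62, 1.45,  52.50, 6.62, 4.39,
    69.58, 6.62, 8.99,  41.66, 6.62, 2.27,  30.83, 6.62, 0.79,
    # N = 5 (T = 11.37 s)
    83.75, 11.37, 8.27,  70.83, 11.37, 5.47,  71.66, 11.37, 5.63,
    93.75, 11.37, 11.10, 52.08, 11.37, 2.50,  86.25, 11.37, 8.91,
    95.85, 11.37, 11.82, 81.25, 11.37, 7.67,  45.83, 11.37, 1.75,
    # N = 10 (T = 17.75 s)
    95, 17.75, 7.38,  89.16, 17.75, 6.21,  88.33, 17.75, 6.06,
    100, 17.75, 8.74, 69.58, 17.75, 3.35,  98.33, 17.75, 8.19,
    99.16, 17.75, 8.44, 90.41, 17.75, 6.44, 70.41, 17.75, 3.45,
    # N = 15 (T = 23.87 s)
    99.58, 23.87, 6.37, 95, 23.87, 5.49, 100, 23.87, 6.50,
    73.75, 23.87, 2.88, 98.33, 23.87, 6.09, 77.08, 23.87, 3.21,
    # N = 20 (T = 30.5 s)
    100, 30.5, 5.09, 79.16, 30.5, 2.68, 87.50, 30.5, 3.44
  )
  got <- wolpaw_itr(6, cells$acc / 100, cells$t_s, digits = 2)
  expect_true(all(abs(got - cells$printed) <= 0.011))
})

test_that("the Wolpaw rate has the right shape and edge behavior", {
  expect_equal(wolpaw_itr(6, 1 / 6, 10), 0, tolerance = 1e-12)
  # monotone increasing in P above chance at fixed T
  ps <- seq(1 / 6, 1, length.out = 30)
  expect_true(all(diff(wolpaw_itr(6, ps, 30.5)) > 0))
  # inversely proportional to T at fixed P
  expect_equal(wolpaw_itr(6, 0.9, 10), 2 * wolpaw_itr(6, 0.9, 20),
               tolerance = 1e-12)
  expect_error(wolpaw_itr(6, 0.9, 0), "positive")
  expect_error(wolpaw_itr(1, 0.9, 10), "n_classes")
  expect_error(wolpaw_itr(6, 1.2, 10), "accuracy")
})

test_that("selection accuracy is exact and display-truncated like the tables", {
  # the worked example: 8 of 12 selections correct
  grid <- c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
            FALSE, FALSE, TRUE, TRUE)
  acc <- selection_accuracy(grid)
  expect_equal(acc, 100 * 8 / 12)
  expect_equal(accuracy_display(acc), 66)
  expect_equal(selection_accuracy(rep(TRUE, 5)), 100)
  expect_equal(selection_accuracy(rep(FALSE, 5)), 0)
  expect_error(selection_accuracy(logical(0)), "no selections")

  # averaging the two sessions' unrounded accuracies matches the
  # blink-table's maximal-N entry to printed precision
  expect_equal(round(mean(c(100 * 8 / 12, 100 * 11 / 12)), 2), 79.17)
  expect_lt(abs(mean(c(100 * 8 / 12, 100 * 11 / 12)) - 79.16), 0.011)
})

test_that("Likert summaries use mean and population SD", {
  expectation <- summarize_likert(c(4, 5, 5, 4, 3, 4, 5, 5, 5, 3))
  expect_equal(expectation$mean, 4.3)
  expect_equal(round(expectation$sd, 2), 0.78)
  control <- summarize_likert(c(5, 5, 3, 5, 5, 5, 5, 3, 5, 5))
  expect_equal(control$mean, 4.6)
  expect_equal(round(control$sd, 2), 0.80)
  expect_equal(summarize_likert(rep(4, 8))$sd, 0)
  expect_error(summarize_likert(c(3, 6)), "1..5")
  expect_error(summarize_likert(integer(0)), "non-empty")
})

# deterministic label fixture: 24 selections, 6 stimuli x 20 epochs each,
# target hit rate high enough that full votes are always right
make_cohort_labels <- function(p_hit = 0.6, p_fa = 0.05, seed = 31) {
  withr::with_seed(seed, {
    targets <- tibble::tibble(block_id = 1:24,
                              target_id = sample(0:5, 24, replace = TRUE))
    labels <- purrr::map_dfr(1:24, function(b) {
      purrr::map_dfr(0:5, function(s) {
        p <- if (s == targets$target_id[b]) p_hit else p_fa
        tibble::tibble(block_id = b, stimulus_id = s,
                       label = stats::rbinom(20, 1, p))
      })
    })
    list(labels = labels, targets = targets)
  })
}

test_that("blink subsampling is exhaustive at maximal N and errors beyond", {
  fx <- make_cohort_labels()
  full_acc <- selection_accuracy(score_labels(fx$labels, fx$targets))
  sub <- subsample_accuracy(fx$labels, fx$targets, n_blinks = 20, seed = 1)
  expect_equal(sub$mean_accuracy, full_acc)
  expect_equal(sub$sd_accuracy, 0)
  expect_error(subsample_accuracy(fx$labels, fx$targets, 21), "exceeds")
})

test_that("perfect labels give 100% at every N and the curve composes", {
  perfect <- make_cohort_labels(p_hit = 1, p_fa = 0)
  curve <- blink_curve(perfect$labels, perfect$targets, seed = 2)
  expect_equal(nrow(curve), 5)
  expect_true(all(curve$mean_accuracy == 100))
  expect_equal(curve$response_time_s,
               unname(default_response_times()), ignore_attr = TRUE)
  # the curve's ITR column is exactly the Wolpaw recomputation
  expect_equal(curve$itr_bits_min,
               wolpaw_itr(6, curve$mean_accuracy / 100, curve$response_time_s))
  expect_error(blink_curve(perfect$labels, perfect$targets, n_blinks = c(1, 7)),
               "response time")
})

test_that("channel feature counts conserve totals and localize", {
  fmap <- tibble::tibble(feature = 1:6,
                         channel = rep(c("Oz", "Fz"), each = 3),
                         time_ms = rep(c(200, 300, 400), 2))
  only_oz <- new_swlda_model(c(1L, 3L), c(1, 1), 0, feature_map = fmap)
  counts <- channel_feature_counts(only_oz)
  expect_equal(counts$n_features[counts$channel == "Oz"], 2L)
  expect_equal(counts$n_features[counts$channel == "Fz"], 0L)

  other <- new_swlda_model(c(2L, 4L, 5L), c(1, 1, 1), 0, feature_map = fmap)
  both <- channel_feature_counts(list(only_oz, other), fmap)
  expect_equal(sum(both$n_features), 5L)
  bad <- new_swlda_model(9L, 1, 0, feature_map = fmap)
  expect_error(channel_feature_counts(bad), "outside the feature map")
})
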