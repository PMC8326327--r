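test_that("stepwise entry matches an exhaustive single-feature oracle", {
  set.seed(21)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(stats::rnorm(n * 51), n, 51)
  X[, 7] <- y  # exact predictor among 50 noise columns

  # oracle: p-value of each single-feature regression
  oracle_p <- suppressWarnings(vapply(seq_len(ncol(X)), function(j) {
    stats::summary.lm(stats::lm(y ~ X[, j]))$coefficients[2, 4]
  }, numeric(1)))
  sel <- stepwise_select(X, y)
  expect_equal(sel[1], which.min(oracle_p))
  expect_equal(sel[1], 7L)
})

test_that("the stepwise path follows greedy best-partial-p on tiny instances", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 40
    X <- matrix(stats::rnorm(n * 5), n, 5)
    y <- as.numeric(X[, 2] + 0.5 * X[, 4] + stats::rnorm(n) > 0)
    if (length(unique(y)) < 2) next
    sel <- stepwise_select(X, y, p_enter = 0.05, p_remove = 1 - 1e-9,
                           max_features = 5)
    # greedy oracle: repeatedly add the candidate with smallest partial p
    inc <- integer(0)
    repeat {
      avail <- setdiff(1:5, inc)
      if (!length(avail)) break
      ps <- vapply(avail, function(j) {
        fit <- stats::summary.lm(stats::lm(y ~ X[, c(inc, j)]))
        fit$coefficients[nrow(fit$coefficients), 4]
      }, numeric(1))
      if (min(ps) >= 0.05) break
      inc <- c(inc, avail[which.min(ps)])
    }
    expect_equal(sel, inc)
  }
})

test_that("null features enter at about the nominal rate", {
  # single candidate, pure noise: entry is a 5%-level test
  set.seed(99)
  hits <- vapply(1:400, function(i) {
    y <- rep(c(0, 1), each = 20)
    x <- matrix(stats::rnorm(40), 40, 1)
    length(stepwise_select(x, y)) > 0
  }, logical(1))
  # binomial(400, 0.05) band
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("stepwise selection is deterministic, capped, and validated", {
  set.seed(5)
  X <- matrix(stats::rnorm(50 * 10), 50, 10)
  y <- as.numeric(X[, 3] > 0)
  expect_identical(stepwise_select(X, y), stepwise_select(X, y))
  expect_identical(stepwise_select(X, y, max_features = 0), integer(0))
  expect_error(stepwise_select(X, rep(1, 50)), "both classes")
  expect_error(stepwise_select(X, y, p_enter = 0.2, p_remove = 0.1), "p_remove")

  # duplicated best column: lowest index wins, duplicate never enters
  X2 <- cbind(y + stats::rnorm(50, sd = 0.1))
  X2 <- cbind(X2, X2[, 1], matrix(stats::rnorm(50 * 3), 50, 3))
  expect_message(sel <- stepwise_select(X2, y), "degenerate")
  expect_equal(sel[1], 1L)
  expect_false(2L %in% sel)
})

test_that("the final model keeps every selected feature below p_remove", {
  model <- model_default()
  expect_gt(length(model$selected), 0)
  expect_true(all(model$p_values < model$p_remove))
})

test_that("the linear rule centers symmetric classes and is deterministic", {
  x <- matrix(c(-2, -1, -1.5, 1, 2, 1.5), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  m <- fit_linear(x, y, selected = 1)
  # symmetric classes: the score at the midpoint (x = 0) is 0.5
  expect_equal(predict_score(m, matrix(0, 1, 1)), 0.5, tolerance = 1e-12)
  # perfectly separated clusters classify the training set exactly
  expect_equal(predict_label(m, x), y)
  m2 <- fit_linear(x, y, selected = 1)
  expect_identical(m$weights, m2$weights)
  expect_error(fit_linear(cbind(x, x), y, selected = c(1, 2)), "singular")
})

test_that("hard labels follow the >= threshold rule and degenerate model warns", {
  m <- new_swlda_model(selected = 1L, weights = 1, intercept = 0,
                       threshold = 0.5)
  expect_equal(predict_label(m, matrix(0.5, 1, 1)), 1L)  # tie labels 1
  expect_equal(predict_label(m, matrix(0.4999, 1, 1)), 0L)
  expect_error(predict_label(m, matrix(0, 1, 0)), "cover")

  m0 <- new_swlda_model(integer(0), numeric(0), 0)
  expect_warning(lab <- predict_label(m0, matrix(0, 3, 2)), "empty")
  expect_equal(lab, rep(0L, 3))
})

test_that("high-SNR epochs classify above 90% and selection sits posterior", {
  model <- hisnr_model()
  ep <- preprocess_session(hisnr_online())
  fm <- to_features(ep)
  truth <- dplyr::left_join(fm$info,
                            hisnr_online()$targets[, c("block_id", "target_id")],
                            by = "block_id")
  y <- as.integer(truth$stimulus_id == truth$target_id)
  acc <- mean(predict_label(model, fm) == y)
  expect_gt(acc, 0.9)

  # selected features concentrate on high-topography (posterior) channels
  topo <- erp_template()$topography
  sel_ch <- tidy(model)$channel
  expect_gt(mean(topo[sel_ch]), mean(topo))
})

test_that("training is deterministic given the session", {
  m1 <- train_swlda(train_epochs_default())
  m2 <- model_default()
  expect_identical(m1$selected, m2$selected)
  expect_identical(m1$weights, m2$weights)
})
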