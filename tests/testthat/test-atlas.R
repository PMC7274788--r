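test_that("training-cell curation follows the percentile + contamination rules", {
  feat <- withr::with_seed(1, matrix(rnorm(3000), 300, 10))
  intens <- c(rep(0, 100), rep(1, 200))
  kept <- select_training_cells(feat, intens, seed = 2)
  expect_length(kept, 190)   # 200 pass the percentile, minus floor(0.05*200)
  expect_true(all(intens[kept] == 1))

  # all intensities equal: the percentile filter keeps everything
  kept2 <- select_training_cells(feat, rep(3, 300), seed = 3)
  expect_length(kept2, 300 - floor(0.05 * 300))

  expect_error(select_training_cells(feat[1:40, ], rep(1:2, 20),
                                     min_cells = 39),
               "survive curation")
})

test_that("isolation forest removes a planted extreme outlier", {
  feat <- withr::with_seed(4, matrix(rnorm(2000), 200, 10))
  feat[7, ] <- feat[7, ] * 100
  hits <- sum(vapply(1:100, function(s) {
    kept <- select_training_cells(feat, rep(1:2, 100), percentile = 0, seed = s)
    !(7 %in% kept)
  }, logical(1)))
  expect_gte(hits, 95)
})

test_that("channel regression: recoverable signal, honest noise floor, CV discipline", {
  withr::with_seed(5, {
    X <- matrix(rnorm(300 * 20), 300, 20)
    B <- matrix(rnorm(20 * 5), 20, 5)
  })
  r <- train_channel_regressor(X, X %*% B, seed = 6)
  expect_gt(r$report$ev_test_mean, 0.95)

  Yn <- withr::with_seed(7, matrix(rnorm(300 * 5), 300, 5))
  rn <- train_channel_regressor(X, Yn, seed = 8)
  expect_lt(abs(rn$report$ev_test_mean), 0.1)

  # test rows disjoint from training rows in every fold
  for (sp in r$report$folds)
    expect_length(intersect(sp$train, sp$test), 0)

  expect_error(train_channel_regressor(X[1:10, ], X %*% B), "matched rows")
})

test_that("noise-floor explained variance is centered at zero across seeds", {
  X <- withr::with_seed(9, matrix(rnorm(150 * 10), 150, 10))
  grid1 <- expand.grid(cost = c(0.1, 1, 10), gamma = 0.1, epsilon = 0.1)
  evs <- vapply(1:20, function(s) {
    Y <- withr::with_seed(100 + s, matrix(rnorm(150 * 2), 150, 2))
    train_channel_regressor(X, Y, grid = grid1, seed = s)$report$ev_test_mean
  }, numeric(1))
  expect_lt(abs(mean(evs)), 0.05)
})

test_that("channel prediction is deterministic and standardization-aware", {
  withr::with_seed(10, {
    X <- matrix(rnorm(200 * 8), 200, 8)
    B <- matrix(rnorm(8 * 3), 8, 3)
  })
  r <- train_channel_regressor(X, X %*% B, seed = 11)
  # training rows of a noiseless fixture are reproduced closely
  pred <- predict_channel(r$model, X)
  ev <- 1 - mean(apply(X %*% B - pred, 2, var) / apply(X %*% B, 2, var))
  expect_gt(ev, 0.95)
  # duplicated inputs give identical predictions
  expect_identical(predict_channel(r$model, X[c(1, 1), ]),
                   predict_channel(r$model, X[c(1, 1), ]))
  expect_equal(pred[c(1, 1), ], predict_channel(r$model, X[c(1, 1), ]),
               ignore_attr = TRUE)
  # the model is nonlinear in the original units: scaling inputs changes
  # predictions (the stored standardization is applied internally)
  expect_false(isTRUE(all.equal(predict_channel(r$model, 2 * X[1:5, ]),
                                2 * pred[1:5, ])))
  expect_error(predict_channel(r$model, X[, 1:4]), "mismatch")
})

test_that("spot-count regression uses the 23-feature input and tracks noise", {
  n <- 250
  withr::with_seed(12, {
    tfor <- matrix(rnorm(n * 10), n, 10)
    cfor <- matrix(rnorm(n * 10), n, 10)
    cen <- matrix(rnorm(n * 3), n, 3)
  })
  signal <- 10 + 5 * sin(cen[, 3]) + 2 * tfor[, 1]
  grid1 <- expand.grid(cost = c(0.1, 1, 10), gamma = 1 / 23, epsilon = 0.1)
  evs <- vapply(c(4, 1, 0.1), function(noise_sd) {
    counts <- withr::with_seed(13, pmax(0, round(signal + rnorm(n, 0, noise_sd))))
    train_count_regressor(tfor, cfor, cen, counts, grid = grid1,
                          seed = 14)$report$ev_test_mean
  }, numeric(1))
  expect_true(all(diff(evs) > 0))   # skill rises as noise falls
  expect_gt(evs[3], 0.5)

  counts_rand <- withr::with_seed(15, rpois(n, 5))
  r0 <- train_count_regressor(tfor, cfor, cen, counts_rand, grid = grid1,
                              seed = 16)
  expect_lt(abs(r0$report$ev_test_mean), 0.15)
  expect_identical(r0$model$n_features, 23L)

  expect_error(train_count_regressor(tfor, cfor, cen, rep(-1, n)),
               "non-negative")
})

test_that("sample filtering by mean spot count is boundary-inclusive", {
  counts <- data.frame(
    sample_id = rep(c("a", "b", "c", "d", "e"), times = c(3, 2, 4, 2, 3)),
    count = c(1, 1, 1,  0, 4,  2, 3, 2, 1,  0, 1,  5, 6, 7))
  keep <- filter_samples_by_mean_count(counts)
  expect_setequal(keep, c("b", "c", "e"))   # means 2, 2, 6; a = 1, d = 0.5
  expect_warning(filter_samples_by_mean_count(
    data.frame(sample_id = "a", count = 0)), "no samples")
})

test_that("nonlinear links favor the RBF regressor over linear baselines", {
  withr::with_seed(17, {
    X <- matrix(rnorm(250 * 5), 250, 5)
    Y <- cbind(sin(2 * X[, 1]) + X[, 2]^2, cos(X[, 3]))
  })
  ev_svr <- train_channel_regressor(X, Y, seed = 18)$report$ev_test_mean
  ev_lin <- train_channel_regressor(X, Y, regressor = "linear",
                                    seed = 18)$report$ev_test_mean
  expect_gte(ev_svr, ev_lin)
})
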