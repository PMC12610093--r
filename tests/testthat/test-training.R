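test_that("cross-entropy matches hand-evaluated cases", {
  expect_equal(cross_entropy_loss(matrix(0, 1, 4), 1), log(4), tolerance = 1e-12)
  # certainty drives the loss to zero
  expect_lt(cross_entropy_loss(matrix(c(50, 0, 0), 1), 1), 1e-12)
  # batch of two: one uniform binary, one certain-correct
  logits <- rbind(c(0, 0), c(100, 0))
  expect_equal(cross_entropy_loss(logits, c(1, 1)), log(2) / 2, tolerance = 1e-9)
  expect_error(cross_entropy_loss(matrix(0, 1, 4), 5), "range")
  expect_error(cross_entropy_loss(matrix(0, 2, 4), 1), "batch sizes")
})

test_that("the learning-rate schedule follows its closed form", {
  tc <- train_config(learning_rate = 1e-3, lr_step = 50, lr_gamma = 0.5)
  expect_equal(lr_schedule(tc, c(0, 49, 50, 100)),
               c(0.001, 0.001, 0.0005, 0.00025))
  tc2 <- train_config(learning_rate = 0.01, lr_step = 10, lr_gamma = 0.1)
  e <- 0:35
  expect_equal(lr_schedule(tc2, e), 0.01 * 0.1^(e %/% 10))
})

test_that("training is deterministic and records the schedule exactly", {
  ts <- random_trialset(n = 12, seed = 41)
  cfg <- tiny_config(dropout = 0.3)
  tc <- train_config(epochs = 6, lr_step = 2, lr_gamma = 0.5, batch_size = 4,
                     seed = 17)
  f1 <- train_model(build_model(cfg, seed = 2), ts, tc)
  f2 <- train_model(build_model(cfg, seed = 2), ts, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$theta, f2$model$theta)
  expect_equal(f1$history$lr, lr_schedule(tc, f1$history$epoch))
  expect_equal(nrow(f1$history), 6)
})

test_that("training reduces the loss on separable synthetic data", {
  ts <- generate_trialset(synth_config(n_classes = 3, n_channels = 6,
                                       n_timepoints = 64, sampling_rate = 64,
                                       trials_per_class = 10, snr = 10,
                                       coupling = 0, seed = 19))
  st <- zscore_fit(ts)
  ts <- zscore_apply(ts, st)
  fit <- train_model(build_model(tiny_config(dropout = 0.1), seed = 3), ts,
                     train_config(epochs = 20, batch_size = 10, seed = 5))
  h <- fit$history
  expect_lt(stats::median(tail(h$loss, 2)), h$loss[1])
  expect_gt(tail(h$accuracy, 1), h$accuracy[1])
})

test_that("training rejects invalid inputs", {
  cfg <- tiny_config()
  model <- build_model(cfg, seed = 1)
  ts <- random_trialset(n = 4, ch = 5, seed = 1)   # wrong channel count
  expect_error(train_model(model, ts, train_config(epochs = 1)), "geometry")
  bad_labels <- random_trialset(n = 4, m = 3, seed = 1)
  bad_labels$labels <- c(1L, 2L, 3L, 9L)
  expect_error(train_model(model, bad_labels, train_config(epochs = 1)),
               "classes")
})

test_that("prediction returns consistent classes, logits and probabilities", {
  model <- tiny_model(seed = 12)
  ts <- random_trialset(n = 5, seed = 14)
  lg <- predict(model, ts, type = "logits")
  pr <- predict(model, ts, type = "prob")
  cl <- predict(model, ts, type = "class")
  expect_equal(dim(lg), c(5, 3))
  expect_equal(rowSums(pr), rep(1, 5), tolerance = 1e-9)
  expect_equal(cl, apply(lg, 1, which.max))
  tab <- prediction_table(model, ts)
  expect_equal(tab$predicted_label, as.integer(cl))
  expect_named(tab, c("trial", "true_label", "predicted_label",
                      paste0("logit_", 1:3)))
})
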