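test_that("model configuration validates the architecture constraints", {
  expect_error(model_config(8, 256, 256, 4, k = 10, h = 4), "divisible")
  expect_error(model_config(8, 256, 256, 4, fusion = "mean"), "should be one of")
  cfg <- model_config(8, 256, 256, 4, k = 16, h = 4)
  expect_equal(cfg$seq_len, 512L)
  expect_equal(cfg$dropout, 0.3)
  # geometry too small for valid convolution + pooling
  expect_error(model_config(2, 20, 256, 2), "temporal kernel|pooled")
})

test_that("parameter count matches hand arithmetic for a known configuration", {
  cfg <- tiny_config()  # ch 6, t 64, fs 64, k 4, h 2, L 32, fc 8, m 3
  model <- build_model(cfg, seed = 1)
  kt <- 6; kc <- 3; k <- 4
  expected <- (kt * k) + (k * kc * k) + 2 * k +        # temporal path + BN
    (kc * k) + (k * kt * k) + 2 * k +                  # spatial path + BN
    2 * 3 * (k * k + k) + 2 + 2 * k +                  # CCA projections, alpha/beta, LN
    4 * (k * k + k) +                                  # MHA q/k/v/out projections
    (32 * k * 8 + 8) + (8 * 3 + 3)                     # classifier head
  expect_equal(count_parameters(model), expected)
  # a single affine map in -> out with bias contributes in*out + out
  lay <- model$layout
  expect_equal(lay$size[lay$name == "W_fc2"] + lay$size[lay$name == "b_fc2"],
               8 * 3 + 3)
})

test_that("module removal strictly reduces the parameter count", {
  full <- build_model(tiny_config(), seed = 1)
  no_gfem <- build_model(tiny_config(variant = "no_gfem"), seed = 1)
  no_lfem <- build_model(tiny_config(variant = "no_lfem"), seed = 1)
  expect_lt(count_parameters(no_gfem), count_parameters(full))
  expect_lt(count_parameters(no_lfem), count_parameters(full))
  expect_gt(count_macs(full), count_macs(no_gfem))
})

test_that("every variant x fusion combination builds and runs forward", {
  x <- matrix(rnorm(6 * 64), 6, 64)
  for (variant in c("full", "no_lfem", "no_gfem")) {
    for (fusion in c("cca", "sum", "cat", "atten")) {
      model <- build_model(tiny_config(variant = variant, fusion = fusion),
                           seed = 2)
      out <- forward_trial(model, x)
      expect_length(out$logits, 3)
      expect_true(all(is.finite(out$logits)))
      expect_true(out$predicted_label %in% 1:3)
    }
  }
})

test_that("the compiled forward pass reproduces the R reference exactly", {
  withr::with_seed(21, {
    x <- matrix(rnorm(6 * 64), 6, 64)
    ts <- eeg_trialset(array(x, c(1, 6, 64)), 1L, 64)
    for (variant in c("full", "no_lfem", "no_gfem")) {
      for (fusion in c("cca", "sum", "cat", "atten")) {
        model <- build_model(tiny_config(variant = variant, fusion = fusion),
                             seed = 3)
        r_logits <- forward_trial(model, x)$logits
        c_logits <- predict(model, ts, type = "logits")[1, ]
        expect_lt(max(abs(r_logits - c_logits)), 1e-10)
      }
    }
  })
})

test_that("analytic gradients match finite differences", {
  withr::with_seed(31, {
    for (spec_ in list(c("full", "cca"), c("no_lfem", "atten"),
                       c("no_gfem", "cat"))) {
      cfg <- tiny_config(variant = spec_[1], fusion = spec_[2])
      model <- build_model(cfg, seed = 5)
      n <- 3
      X <- aperm(array(rnorm(n * 6 * 64), c(n, 6, 64)), c(2, 3, 1))
      y <- sample(1:3, n, replace = TRUE)
      lg <- eegcca:::cpp_loss_grad(model$theta, model$state, unclass(cfg), X, y, 1L)
      idx <- sort(sample(length(model$theta), 25))
      eps <- 1e-6
      num <- vapply(idx, function(j) {
        tp <- model$theta; tp[j] <- tp[j] + eps
        tm <- model$theta; tm[j] <- tm[j] - eps
        (eegcca:::cpp_loss_grad(tp, model$state, unclass(cfg), X, y, 1L)$loss -
           eegcca:::cpp_loss_grad(tm, model$state, unclass(cfg), X, y, 1L)$loss) /
          (2 * eps)
      }, numeric(1))
      rel <- max(abs(num - lg$grad[idx]) / pmax(1e-4, abs(num) + abs(lg$grad[idx])))
      expect_lt(rel, 1e-4)
    }
  })
})

test_that("initialisation is reproducible and seed-sensitive", {
  m1 <- build_model(tiny_config(), seed = 9)
  m2 <- build_model(tiny_config(), seed = 9)
  m3 <- build_model(tiny_config(), seed = 10)
  expect_identical(m1$theta, m2$theta)
  expect_false(identical(m1$theta, m3$theta))
})
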