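identity_proj <- function(k) {
  list(Wq = diag(k), bq = rep(0, k), Wk = diag(k), bk = rep(0, k),
       Wv = diag(k), bv = rep(0, k), dk = k)
}

rand_seq <- function(L, k, role = "temporal", seed = 1) {
  withr::with_seed(seed, feature_seq(matrix(rnorm(L * k), L, k), role))
}

test_that("cross-attention directions reduce to self-attention on equal inputs", {
  k <- 4; L <- 8
  f <- rand_seq(L, k)
  proj <- identity_proj(k)
  fts <- cross_attention_ts(f, feature_seq(unclass(f), "spatial"), proj)
  self <- scaled_dot_product_attention(unclass(f), unclass(f), unclass(f), k)
  expect_equal(unclass(fts), self, tolerance = 1e-12, ignore_attr = TRUE)
  fst <- cross_attention_st(feature_seq(unclass(f), "spatial"), f, proj)
  expect_equal(unclass(fst), unclass(fts), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("cross-attention has the contracted shape and direction asymmetry", {
  model <- tiny_model(seed = 3)
  ft <- rand_seq(32, 4, "temporal", 5)
  fs <- rand_seq(32, 4, "spatial", 6)
  fts <- cross_attention_ts(ft, fs, attention_projections(model, "ts"))
  fst <- cross_attention_st(fs, ft, attention_projections(model, "st"))
  expect_equal(dim(unclass(fts)), c(32, 4))
  expect_equal(dim(unclass(fst)), c(32, 4))
  expect_gt(max(abs(unclass(fts) - unclass(fst))), 0)
  expect_error(cross_attention_ts(ft, feature_seq(matrix(0, 16, 4), "spatial"),
                                  attention_projections(model, "ts")),
               "identical shape")
})

test_that("attention output is invariant to permuting key/value positions", {
  model <- tiny_model(seed = 4)
  ft <- rand_seq(32, 4, "temporal", 7)
  fs <- rand_seq(32, 4, "spatial", 8)
  proj <- attention_projections(model, "ts")
  base <- cross_attention_ts(ft, fs, proj)
  perm <- withr::with_seed(1, sample(32))
  fs_perm <- feature_seq(unclass(fs)[perm, ], "spatial")
  expect_equal(unclass(cross_attention_ts(ft, fs_perm, proj)), unclass(base),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("fusion applies weighted sum and layer normalisation", {
  k <- 2; L <- 4
  fts <- feature_seq(matrix(c(1, 3), L, k, byrow = TRUE), "temporal")
  fst <- feature_seq(matrix(c(3, 5), L, k, byrow = TRUE), "spatial")
  out <- fuse(fts, fst, list(alpha = 0.5, beta = 0.5, gain = c(1, 1), shift = c(0, 0)))
  # pre-LN rows are (2, 4): mean 3, population sd 1 -> (-1, 1)
  expect_equal(unclass(out), matrix(c(-1, 1), L, k, byrow = TRUE),
               tolerance = 1e-4, ignore_attr = TRUE)

  # alpha = 1, beta = 0 collapses to LN(fts)
  a <- rand_seq(8, 3, "temporal", 2)
  b <- rand_seq(8, 3, "spatial", 3)
  w10 <- list(alpha = 1, beta = 0, gain = rep(1, 3), shift = rep(0, 3))
  expect_equal(unclass(fuse(a, b, w10)), layer_norm(unclass(a)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # constant sequences normalise to zero
  cc <- feature_seq(matrix(7, 8, 3), "temporal")
  expect_equal(max(abs(fuse(cc, cc))), 0)
  expect_equal(attr(fuse(a, b), "role"), "fused")
})

test_that("baseline fusion strategies satisfy their contracts", {
  ft <- rand_seq(16, 4, "temporal", 9)
  fs <- rand_seq(16, 4, "spatial", 10)
  zero <- feature_seq(matrix(0, 16, 4), "spatial")

  expect_equal(unclass(fusion_baseline(ft, zero, "sum")), unclass(ft),
               ignore_attr = TRUE)

  W <- matrix(rnorm(8 * 4), 8, 4); bvec <- rnorm(4)
  catted <- fusion_baseline(ft, fs, "cat", weights = list(Wcat = W, bcat = bvec))
  expect_equal(dim(unclass(catted)), c(16, 4))
  expect_equal(unclass(catted),
               cbind(unclass(ft), unclass(fs)) %*% W +
                 matrix(bvec, 16, 4, byrow = TRUE),
               ignore_attr = TRUE)

  Wat <- matrix(rnorm(8 * 2), 8, 2); bat <- rnorm(2)
  at <- fusion_baseline(ft, fs, "atten", weights = list(Wat = Wat, bat = bat),
                        return_weights = TRUE)
  expect_equal(sum(at$weights), 1, tolerance = 1e-12)
  expect_true(all(at$weights > 0 & at$weights < 1))
  expect_equal(unclass(at$fused),
               at$weights[1] * unclass(ft) + at$weights[2] * unclass(fs),
               ignore_attr = TRUE)

  expect_error(fusion_baseline(ft, fs, "concat"), "sum, cat, atten")
})

test_that("fusion scalars receive gradient during training", {
  cfg <- tiny_config(fusion = "cca")
  model <- build_model(cfg, seed = 11)
  ts <- random_trialset(n = 4, seed = 13)
  cube <- aperm(ts$data, c(2, 3, 1))
  lg <- eegcca:::cpp_loss_grad(model$theta, model$state, unclass(cfg),
                               cube, ts$labels, 1L)
  lay <- model$layout
  g_alpha <- lg$grad[lay$offset[lay$name == "alpha"] + 1]
  g_beta <- lg$grad[lay$offset[lay$name == "beta"] + 1]
  expect_gt(abs(g_alpha), 0)
  expect_gt(abs(g_beta), 0)
})
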