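test_that("ELU matches its closed form", {
  expect_equal(elu(-1), exp(-1) - 1, tolerance = 1e-12)
  expect_equal(elu(0), 0)
  expect_equal(elu(2.5), 2.5)
  expect_equal(elu(c(-2, 0, 3)), c(exp(-2) - 1, 0, 3))
})

test_that("softmax rows are shift-invariant and stochastic", {
  set.seed(1)
  x <- matrix(rnorm(5 * 4), 5, 4)
  p <- softmax_rows(x)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
  expect_true(all(p > 0))
  expect_equal(softmax_rows(x + 1000), p, tolerance = 1e-9)
})

test_that("scaled dot-product attention matches a brute-force oracle", {
  set.seed(42)
  for (rep in 1:100) {
    n_q <- sample(1:8, 1); n_k <- sample(1:8, 1); k <- sample(1:4, 1)
    Q <- matrix(rnorm(n_q * k), n_q, k)
    K <- matrix(rnorm(n_k * k), n_k, k)
    V <- matrix(rnorm(n_k * k), n_k, k)
    expect_lt(max(abs(scaled_dot_product_attention(Q, K, V, k) -
                        naive_attention(Q, K, V, k))), 1e-6)
  }
})

test_that("attention hand-worked examples hold", {
  # singleton key/value: output equals the single value row for any query
  Q <- matrix(rnorm(6), 3, 2)
  K <- matrix(c(0.3, -1), 1, 2)
  V <- matrix(c(5, 7), 1, 2)
  out <- scaled_dot_product_attention(Q, K, V)
  expect_equal(out, matrix(rep(c(5, 7), each = 3), 3, 2))

  # identical key rows: output is the unweighted mean of the value rows
  K2 <- matrix(1, 4, 2)
  V2 <- matrix(rnorm(8), 4, 2)
  out2 <- scaled_dot_product_attention(Q, K2, V2)
  expect_equal(out2[1, ], colMeans(V2), tolerance = 1e-12)

  # k = 1 case evaluated by hand through the softmax
  Q3 <- matrix(c(1, 0), 2, 1); K3 <- matrix(c(1, 0), 2, 1)
  V3 <- matrix(c(2, 4), 2, 1)
  out3 <- scaled_dot_product_attention(Q3, K3, V3, dk = 1)
  expect_equal(out3[1, 1], (exp(1) * 2 + 4) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(out3[2, 1], 3)

  w <- scaled_dot_product_attention(Q3, K3, V3, dk = 1, return_weights = TRUE)
  expect_equal(rowSums(w$weights), c(1, 1))
  expect_error(scaled_dot_product_attention(matrix(NA_real_, 1, 1), K3, V3),
               "non-finite")
})

test_that("layer normalisation centres and scales each position", {
  x <- matrix(c(1, 3, 3, 5), 2, 2, byrow = FALSE)  # rows: (1,3) and (3,5)
  ln <- layer_norm(x)
  expect_equal(ln[1, ], c(-1, 1), tolerance = 1e-4)  # mean 2, sd 1 (+eps)
  expect_equal(ln[2, ], c(-1, 1), tolerance = 1e-4)
  g <- layer_norm(x, gain = c(2, 2), shift = c(1, 1))
  expect_equal(g, 2 * ln + 1)
  const <- matrix(4, 3, 5)
  expect_equal(max(abs(layer_norm(const))), 0)
})

test_that("sequence mapping preserves shape, constants and the mean", {
  fm <- array(rnorm(3 * 4 * 10), c(3, 4, 10))
  s <- to_sequence(fm, seq_len = 512)
  expect_equal(dim(s), c(512, 3))
  # mean over positions preserved (area-preserving resampling)
  for (f in 1:3) {
    expect_lt(abs(mean(s[, f]) - mean(fm[f, , ])) / (abs(mean(fm[f, , ])) + 1e-9),
              1e-5)
  }
  # exact-length input is a pure rearrangement
  fm2 <- array(rnorm(2 * 4 * 8), c(2, 4, 8))
  s2 <- to_sequence(fm2, seq_len = 32)
  expect_equal(s2[1, ], fm2[, 1, 1])          # position 1 = plane cell (1,1)
  expect_equal(s2[9, ], fm2[, 2, 1])          # row-major: position 9 = cell (2,1)
  expect_equal(sort(s2[, 1]), sort(as.vector(fm2[1, , ])))
  # constants stay constant
  cm <- array(2.5, c(2, 3, 5))
  expect_equal(as.vector(to_sequence(cm, 128)), rep(2.5, 256))
})

test_that("average pooling conserves block means", {
  x <- array(rnorm(2 * 8 * 12), c(2, 8, 12))
  p <- eegcca:::avg_pool2d(x, c(4, 4))
  expect_equal(dim(p), c(2, 2, 3))
  expect_equal(p[1, 2, 3], mean(x[1, 5:8, 9:12]), tolerance = 1e-12)
  # pooled mean equals input mean over the covered region
  covered <- x[2, 1:8, 1:12]
  expect_equal(mean(p[2, , ]), mean(covered), tolerance = 1e-6)
})

test_that("valid convolution computes cross-correlation without padding", {
  x <- array(0, c(1, 3, 5)); x[1, , ] <- matrix(1:15, 3, 5)
  w <- array(0, c(2, 1, 2, 2))
  w[1, 1, , ] <- diag(2)           # picks x[i,j] + x[i+1,j+1]
  w[2, 1, , ] <- matrix(1, 2, 2)   # block sum
  out <- eegcca:::conv2d_valid(x, w)
  expect_equal(dim(out), c(2, 2, 4))
  expect_equal(out[1, 1, 1], x[1, 1, 1] + x[1, 2, 2])
  expect_equal(out[2, 2, 3], sum(x[1, 2:3, 3:4]))
  # linearity
  y <- x; y[1, , ] <- matrix(rnorm(15), 3, 5)
  lhs <- eegcca:::conv2d_valid(array(2 * x + 3 * y, dim(x)), w)
  rhs <- 2 * out + 3 * eegcca:::conv2d_valid(y, w)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})
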