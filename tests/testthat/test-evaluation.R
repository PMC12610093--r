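test_that("stratified folds are balanced partitions", {
  labels <- rep(1:2, each = 5)
  plan <- stratified_kfold(labels, 5, seed = 1)
  expect_length(plan$folds, 5)
  all_test <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  expect_equal(all_test, seq_along(labels))
  for (f in plan$folds) {
    expect_length(f$test, 2)
    expect_length(f$train, 8)
    expect_equal(sort(c(f$train, f$test)), seq_along(labels))
    expect_equal(as.vector(table(labels[f$test])), c(1, 1))
  }
  expect_error(stratified_kfold(c(1, 1, 1, 2, 2, 2, 2, 2), 5), "class 1")
})

test_that("stratification bounds hold for unbalanced classes", {
  withr::with_seed(2, {
    labels <- sample(rep(1:3, times = c(13, 22, 7)))
    plan <- stratified_kfold(labels, 4, seed = 9)
    counts <- sapply(plan$folds, function(f) {
      tabulate(labels[f$test], nbins = 3)
    })
    for (cls in 1:3) {
      expect_lte(diff(range(counts[cls, ])), 1)
    }
    expect_equal(rowSums(counts), c(13, 22, 7))
  })
})

test_that("leave-one-subject-out builds one fold per subject", {
  ids <- c("a", "a", "b", "c", "c", "c")
  plan <- loso_split(ids)
  expect_length(plan$folds, 3)
  expect_equal(sapply(plan$folds, function(f) length(f$test)), c(2, 1, 3))
  all_test <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  expect_equal(all_test, 1:6)
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0)
  }
  expect_error(loso_split(rep("solo", 4)), "2 distinct")
})

test_that("accuracy summary matches a brute-force evaluation", {
  s <- accuracy_summary(c(40, 45, 50, 45, 45))
  expect_equal(s$mean, 45)
  expect_equal(s$sd, 3.1623, tolerance = 1e-4)
  expect_equal(accuracy_summary(c(45, 45, 45, 45, 45)), list(mean = 45, sd = 0))
  expect_equal(accuracy_summary(30), list(mean = 30, sd = 0))
  expect_error(accuracy_summary(numeric(0)), "empty")
  withr::with_seed(5, {
    for (i in 1:20) {
      acc <- runif(sample(2:8, 1), 0, 100)
      brute_mu <- sum(acc) / length(acc)
      brute_sd <- sqrt(sum((acc - brute_mu)^2) / length(acc))
      s2 <- accuracy_summary(acc)
      expect_lt(abs(s2$mean - brute_mu), 1e-9)
      expect_lt(abs(s2$sd - brute_sd), 1e-9)
    }
  })
})

test_that("confusion matrices and macro F1 match hand calculations", {
  perfect <- confusion_and_f1(rep(1:3, each = 4), rep(1:3, each = 4), 3)
  expect_equal(unname(perfect$confusion), diag(3) * 4, ignore_attr = TRUE)
  expect_equal(perfect$f1, 1)

  # binary: TP = 2, FP = 1, FN = 1, TN = 2 -> F1 = 2/3 for both classes
  truth <- c(1, 1, 1, 2, 2, 2)
  pred <- c(1, 1, 2, 1, 2, 2)
  bin <- confusion_and_f1(truth, pred, 2)
  expect_equal(bin$f1, 2 / 3, tolerance = 1e-12)
  expect_equal(as.vector(bin$confusion), c(2, 1, 1, 2))

  # all predictions collapse onto one class
  collapsed <- confusion_and_f1(rep(1:4, each = 3), rep(1, 12), 4)
  expect_equal(collapsed$f1, 0.1, tolerance = 1e-12)
  expect_equal(rowSums(collapsed$confusion), rep(3, 4), ignore_attr = TRUE)

  expect_warning(confusion_and_f1(c(1, 1), c(1, 1), 2), "no support")
  expect_error(confusion_and_f1(1:3, 1:2, 3), "lengths differ")
})

test_that("channel dropout zero-fills and keeps fraction-zero identity", {
  model <- tiny_model(seed = 21)
  ts <- random_trialset(n = 6, seed = 22)
  clean <- 100 * mean(predict(model, ts) == ts$labels)
  expect_equal(channel_dropout_eval(model, ts, 0, seed = 1), clean)
  expect_error(channel_dropout_eval(model, ts, 1), "below 1")
  expect_error(channel_dropout_eval(model, ts, -0.1), "non-negative")
  # the same seed removes the same channels
  a <- channel_dropout_eval(model, ts, 0.4, seed = 3)
  b <- channel_dropout_eval(model, ts, 0.4, seed = 3)
  expect_identical(a, b)
})

test_that("signed-rank test matches full sign enumeration for small n", {
  # constant unit shift, n = 6: W = 0, exact p = 2/64
  a <- c(2, 3, 4, 5, 6, 7)
  w <- wilcoxon_signed_rank(a - 1, a)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 2 / 64)
  expect_equal(w$method, "exact")

  withr::with_seed(7, {
    for (i in 1:15) {
      n <- sample(5:10, 1)
      x <- rnorm(n); y <- rnorm(n)
      mine <- wilcoxon_signed_rank(x, y)$p_value
      expect_equal(mine, enumerate_wilcoxon(x, y), tolerance = 1e-12)
      # symmetry of the two-sided test
      expect_equal(mine, wilcoxon_signed_rank(y, x)$p_value)
    }
  })
})

test_that("signed-rank test agrees with the reference implementation", {
  withr::with_seed(11, {
    for (i in 1:10) {
      x <- rnorm(15); y <- rnorm(15)
      expect_equal(wilcoxon_signed_rank(x, y)$p_value,
                   stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
    # beyond the exact limit: tie-corrected normal approximation
    x <- rnorm(40); y <- rnorm(40)
    approx_p <- wilcoxon_signed_rank(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                              correct = TRUE)$p.value
    expect_equal(approx_p$method, "normal_approximation")
    expect_equal(approx_p$p_value, ref, tolerance = 1e-6)
  })
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "no discriminative")
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("ties are handled exactly through doubled midranks", {
  a <- c(3, 3, 5, 8, 8, 1)
  b <- c(1, 1, 2, 2, 2, 2)   # differences 2, 2, 3, 6, 6, -1 (ties)
  mine <- wilcoxon_signed_rank(a, b)$p_value
  expect_equal(mine, enumerate_wilcoxon(a, b), tolerance = 1e-12)
})
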