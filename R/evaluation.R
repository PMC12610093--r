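#' Stratified k-fold partition
#'
#' Shuffled, class-stratified partition of trial indices into `n_folds`
#' folds: every fold's test set contains `floor(n_c / n_folds)` or
#' `ceiling(n_c / n_folds)` members of class `c`, so class proportions are
#' preserved and per-class test counts across folds differ by at most 1.
#'
#' @param labels Integer class labels in `1..m`.
#' @param n_folds Number of folds (default 5: a 4:1 train-to-test ratio).
#' @param seed Integer seed for the within-class shuffles.
#' @return A `fold_plan`: list with `folds` (each a list with `train` and
#'   `test` index vectors), `scheme = "stratified_kfold"`, and `seed`.
#' @export
stratified_kfold <- function(labels, n_folds = 5L, seed = 1L) {
  labels <- as.integer(labels)
  n_folds <- as.integer(n_folds)
  counts <- table(labels)
  short <- names(counts)[counts < n_folds]
  if (length(short)) {
    stop("class ", paste(short, collapse = ", "), " has fewer than ", n_folds,
         " members; cannot stratify into ", n_folds, " folds", call. = FALSE)
  }
  assign_fold <- integer(length(labels))
  with_local_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- sample(which(labels == cls))
      # deal class members out round-robin so fold sizes differ by at most 1
      assign_fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds <- lapply(seq_len(n_folds), function(f) {
    test <- which(assign_fold == f)
    list(train = setdiff(seq_along(labels), test), test = test)
  })
  structure(list(folds = folds, scheme = "stratified_kfold", seed = as.integer(seed)),
            class = "fold_plan")
}

#' Leave-one-subject-out partition
#'
#' One fold per distinct subject: that subject's trials form the test set
#' and all remaining trials the training set.
#'
#' @param subject_ids Per-trial subject identifiers (>= 2 distinct values).
#' @return A `fold_plan` with `scheme = "loso"`; folds are ordered by the
#'   sorted unique subject ids, and each fold carries its `subject`.
#' @export
loso_split <- function(subject_ids) {
  subject_ids <- as.character(subject_ids)
  subjects <- sort(unique(subject_ids))
  if (length(subjects) < 2L) {
    stop("leave-one-subject-out requires at least 2 distinct subjects", call. = FALSE)
  }
  folds <- lapply(subjects, function(s) {
    test <- which(subject_ids == s)
    list(train = which(subject_ids != s), test = test, subject = s)
  })
  structure(list(folds = folds, scheme = "loso", seed = NA_integer_),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %s, %d folds\n", x$scheme, length(x$folds)))
  for (i in seq_along(x$folds)) {
    f <- x$folds[[i]]
    cat(sprintf("  fold %d: %d train / %d test%s\n", i, length(f$train),
                length(f$test),
                if (!is.null(f$subject)) paste0(" (subject ", f$subject, ")") else ""))
  }
  invisible(x)
}

#' Summarise per-fold accuracies as mean and standard deviation
#'
#' The mean is the arithmetic mean; the standard deviation uses the
#' population divisor (the fold count, not `n - 1`).
#'
#' @param per_fold Numeric vector of per-fold accuracies (percent).
#' @return Named list with `mean` and `sd`.
#' @examples
#' accuracy_summary(c(40, 45, 50, 45, 45))  # 45 +/- 3.1623
#' @export
accuracy_summary <- function(per_fold) {
  if (length(per_fold) == 0L) stop("empty accuracy list", call. = FALSE)
  mu <- mean(per_fold)
  list(mean = mu, sd = sqrt(mean((per_fold - mu)^2)))
}

#' Confusion matrix and macro-averaged F1
#'
#' Rows of the confusion matrix are true classes, columns predicted classes.
#' Macro F1 is the unweighted mean of per-class F1 scores; a class without
#' support (no true and no predicted members) contributes 0 with a warning.
#'
#' @param true,pred Integer label vectors of equal length.
#' @param m Number of classes.
#' @return List with `confusion` (`m x m` count matrix) and `f1` (macro F1).
#' @export
confusion_and_f1 <- function(true, pred, m) {
  true <- as.integer(true); pred <- as.integer(pred)
  if (length(true) != length(pred)) stop("`true` and `pred` lengths differ", call. = FALSE)
  cm <- matrix(0L, m, m, dimnames = list(true = seq_len(m), pred = seq_len(m)))
  for (i in seq_along(true)) cm[true[i], pred[i]] <- cm[true[i], pred[i]] + 1L
  f1s <- vapply(seq_len(m), function(c) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    if (tp + fp + fn == 0L) {
      warning("class ", c, " has no support; its F1 contributes 0", call. = FALSE)
      return(0)
    }
    if (tp == 0L) return(0)
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  list(confusion = cm, f1 = mean(f1s))
}

#' Accuracy under random channel dropout
#'
#' Zero-fills a random subset of channels in every test trial (shape is
#' preserved, so the spatial convolution geometry is unchanged) and measures
#' accuracy on the degraded input. The number of zeroed channels is
#' `round(fraction * ch)` (round-half-even), at least 1 whenever
#' `fraction > 0`.
#'
#' @param model A trained `cca_net`.
#' @param test An [eeg_trialset()].
#' @param fraction Fraction of channels to remove, in `[0, 1)`; the standard
#'   robustness probe uses 0.05 and 0.10.
#' @param seed Integer seed selecting the removed channels.
#' @return Accuracy in percent on the degraded test set.
#' @export
channel_dropout_eval <- function(model, test, fraction, seed = 1L) {
  if (fraction >= 1) stop("`fraction` must be below 1", call. = FALSE)
  if (fraction < 0) stop("`fraction` must be non-negative", call. = FALSE)
  degraded <- test
  if (fraction > 0) {
    ch <- n_channels(test)
    n_drop <- max(1L, as.integer(round(fraction * ch)))
    drop <- with_local_seed(seed, sample.int(ch, n_drop))
    degraded$data[, drop, ] <- 0
  }
  pred <- predict(model, degraded, type = "class")
  100 * mean(pred == test$labels)
}

#' Exact / approximate Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test. Zero differences are dropped
#' (standard convention). For `n <= exact_limit` retained pairs the p-value
#' comes from the exact null distribution of the signed-rank statistic
#' (computed over all `2^n` sign assignments of the midranks via dynamic
#' programming, which handles ties exactly); beyond that a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b Paired score vectors of equal length.
#' @param exact_limit Largest n for which the exact distribution is used
#'   (default 25).
#' @return List with `statistic` (W, the smaller signed-rank sum), `n`
#'   (retained pairs), `p_value` and `method`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_limit = 25L) {
  if (length(a) != length(b)) stop("paired vectors must have equal length", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("no discriminative pairs: all differences are zero", call. = FALSE)
  r <- rank(abs(d))                       # midranks for ties
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  W <- min(w_pos, w_neg)
  if (n <= exact_limit) {
    # Exact: distribution of the positive-rank sum over all sign vectors.
    # Doubled midranks are integers, enabling a subset-sum DP.
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)         # counts[s + 1] = #assignments with sum s
    counts[1L] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts[seq_len(total + 1L - ri)])
      counts <- counts + shifted
    }
    # two-sided: P(W+ <= min) + P(W+ >= max) on the doubled scale
    lo <- round(2 * W); hi <- round(2 * max(w_pos, w_neg))
    p <- (sum(counts[seq_len(lo + 1L)]) + sum(counts[(hi + 1L):(total + 1L)])) / 2^n
    p <- min(1, p)
    list(statistic = W, n = n, p_value = p, method = "exact")
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    list(statistic = W, n = n, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal_approximation")
  }
}

#' Evaluate a trained model on a test set
#'
#' @param model A trained `cca_net`.
#' @param test An [eeg_trialset()].
#' @param dropout_fractions Channel-dropout fractions for the robustness
#'   probe (default `c(0.05, 0.10)`); use `numeric(0)` to skip.
#' @param seed Seed for the channel-dropout draws.
#' @return Tibble with one row: `accuracy` (percent), `f1` (macro),
#'   `n_test`, plus one `accuracy_drop<pct>` column per dropout fraction;
#'   the confusion matrix is attached as attribute `"confusion"`.
#' @export
evaluate_model <- function(model, test, dropout_fractions = c(0.05, 0.10),
                           seed = 1L) {
  pred <- predict(model, test, type = "class")
  acc <- 100 * mean(pred == test$labels)
  cf <- confusion_and_f1(test$labels, pred, model$config$n_classes)
  out <- tibble::tibble(accuracy = acc, f1 = cf$f1, n_test = n_trials(test))
  for (fr in dropout_fractions) {
    out[[sprintf("accuracy_drop%g", 100 * fr)]] <-
      channel_dropout_eval(model, test, fr, seed)
  }
  attr(out, "confusion") <- cf$confusion
  out
}
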