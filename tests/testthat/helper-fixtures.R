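# Shared fixtures: everything is generated in code at test time.

# a deliberately small network configuration so forward passes are cheap
tiny_config <- function(...) {
  args <- list(channels = 6, timepoints = 64, sampling_rate = 64,
               n_classes = 3, k = 4, h = 2, seq_len = 32, fc_hidden = 8,
               dropout = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

tiny_model <- function(seed = 1, ...) build_model(tiny_config(...), seed = seed)

random_trialset <- function(n = 6, ch = 6, t = 64, fs = 64, m = 3, seed = 1) {
  withr::with_seed(seed, {
    eeg_trialset(array(stats::rnorm(n * ch * t), dim = c(n, ch, t)),
                 labels = rep_len(seq_len(m), n), sampling_rate = fs)
  })
}

# single-trial set holding one pure sinusoid (or constant) trace per channel
tone_trialset <- function(freq, n_time = 2048, fs = 256, channels = 1) {
  tt <- (seq_len(n_time) - 1) / fs
  x <- if (freq == 0) rep(1, n_time) else sin(2 * pi * freq * tt)
  eeg_trialset(array(rep(x, each = channels), dim = c(1, channels, n_time)),
               labels = 1L, sampling_rate = fs)
}

signal_power <- function(ts) mean(ts$data^2)

# brute-force scaled dot-product attention: explicit loops, no linear algebra
naive_attention <- function(Q, K, V, dk) {
  n_q <- nrow(Q); n_k <- nrow(K)
  out <- matrix(0, n_q, ncol(V))
  for (i in seq_len(n_q)) {
    s <- numeric(n_k)
    for (j in seq_len(n_k)) {
      s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    }
    w <- exp(s - max(s))
    w <- w / sum(w)
    for (f in seq_len(ncol(V))) {
      out[i, f] <- sum(w * V[, f])
    }
  }
  out
}

# exact two-sided signed-rank p-value by enumerating all 2^n sign vectors
enumerate_wilcoxon <- function(a, b) {
  d <- (a - b)[a != b]
  n <- length(d)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  wplus <- as.matrix(signs) %*% r
  lo <- min(w_pos, sum(r) - w_pos)
  hi <- max(w_pos, sum(r) - w_pos)
  # when lo == hi the central bin is counted from both tails; a two-sided
  # p-value is capped at 1
  min(1, (sum(wplus <= lo + 1e-9) + sum(wplus >= hi - 1e-9)) / 2^n)
}
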