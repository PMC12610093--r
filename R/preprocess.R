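#' Preprocessing configuration
#'
#' Parameters of the standard EEG conditioning chain: zero-phase Butterworth
#' band-pass, power-line notch, optional re-referencing, and anti-aliased
#' downsampling.
#'
#' @param bandpass_low,bandpass_high Band edges in Hz; must satisfy
#'   `0 < low < high < sampling_rate / 2`.
#' @param notch_freq Notch centre frequency in Hz (50 Hz power line by
#'   default); `NULL` disables the notch.
#' @param target_rate Output sampling rate in Hz; `NULL` keeps the input rate.
#' @param reference_channels Integer channel indices averaged to form the
#'   reference; empty vector means no re-referencing.
#' @param filter_order Butterworth order of the band-pass (default 4).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(bandpass_low = 0.5, bandpass_high = 100,
                              notch_freq = 50, target_rate = NULL,
                              reference_channels = integer(0),
                              filter_order = 4) {
  structure(list(bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 notch_freq = notch_freq, target_rate = target_rate,
                 reference_channels = as.integer(reference_channels),
                 filter_order = as.integer(filter_order)),
            class = "preprocess_config")
}

# Zero-phase filtering with reflection padding to suppress edge transients.
# b, a: filter coefficients; x: numeric vector.
filtfilt_padded <- function(b, a, x) {
  n <- length(x)
  # narrow-band (high-Q) filters ring for a long time; mirror as much of the
  # signal as is available
  pad <- n - 1L
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- signal::filtfilt(signal::Arma(b = b, a = a), xp)
  y[(pad + 1L):(pad + n)]
}

apply_per_trace <- function(ts, fun) {
  d <- dim(ts$data)
  out <- ts$data
  for (i in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      out[i, c, ] <- fun(ts$data[i, c, ])
    }
  }
  res <- ts
  res$data <- out
  res
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to every
#' channel of every trial. Shape, labels and metadata are unchanged.
#'
#' @param ts An [eeg_trialset()].
#' @param low,high Band edges in Hz.
#' @param order Butterworth order (default 4).
#' @return The filtered `eeg_trialset`.
#' @export
bandpass_filter <- function(ts, low, high, order = 4) {
  nyq <- ts$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("band edges must satisfy 0 < low < high < Nyquist (", nyq, " Hz); got [",
         low, ", ", high, "]", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  apply_per_trace(ts, function(x) filtfilt_padded(bf$b, bf$a, x))
}

#' Zero-phase power-line notch filter
#'
#' Second-order IIR notch (quality factor 30) applied forward-backward to
#' every channel of every trial.
#'
#' @param ts An [eeg_trialset()].
#' @param freq Notch centre frequency in Hz (must be below Nyquist).
#' @param q Quality factor (centre frequency / -3 dB bandwidth).
#' @return The filtered `eeg_trialset`.
#' @export
notch_filter <- function(ts, freq, q = 30) {
  nyq <- ts$sampling_rate / 2
  if (freq >= nyq) {
    stop("notch frequency (", freq, " Hz) must be below Nyquist (", nyq, " Hz)",
         call. = FALSE)
  }
  # standard audio-EQ biquad notch
  w0 <- 2 * pi * freq / ts$sampling_rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  b <- b / a[1]; a <- a / a[1]
  apply_per_trace(ts, function(x) filtfilt_padded(b, a, x))
}

#' Re-reference channels to the mean of a reference channel set
#'
#' Subtracts, at every timepoint of every trial, the mean of the reference
#' channels' signal from every channel (e.g. earlobe or CPz referencing). An
#' empty reference set is the identity transform.
#'
#' @param ts An [eeg_trialset()].
#' @param reference_channels Integer indices of the reference channels.
#' @return The re-referenced `eeg_trialset`.
#' @export
rereference <- function(ts, reference_channels) {
  if (length(reference_channels) == 0L) return(ts)
  reference_channels <- as.integer(reference_channels)
  if (any(reference_channels < 1L | reference_channels > n_channels(ts))) {
    stop("reference channel index out of range 1..", n_channels(ts), call. = FALSE)
  }
  out <- ts
  for (i in seq_len(n_trials(ts))) {
    x <- trial_matrix(ts, i)
    ref <- colMeans(x[reference_channels, , drop = FALSE])
    out$data[i, , ] <- sweep(x, 2L, ref)
  }
  out
}

#' Anti-aliased downsampling
#'
#' Polyphase rational resampling of every channel to `target_rate`; the new
#' trial length is `round(t * target_rate / fs)` and the stored sampling rate
#' is updated.
#'
#' @param ts An [eeg_trialset()].
#' @param target_rate Target sampling rate in Hz (`0 < target_rate <= fs`).
#' @return The resampled `eeg_trialset`.
#' @export
downsample <- function(ts, target_rate) {
  if (!is.numeric(target_rate) || target_rate <= 0) {
    stop("`target_rate` must be a positive rate in Hz", call. = FALSE)
  }
  fs <- ts$sampling_rate
  if (target_rate > fs) stop("`target_rate` exceeds the current sampling rate", call. = FALSE)
  if (target_rate == fs) return(ts)
  frac <- ratio_integers(target_rate / fs)
  t_old <- n_timepoints(ts)
  t_new <- round(t_old * target_rate / fs)
  d <- dim(ts$data)
  out_data <- array(0, dim = c(d[1], d[2], t_new))
  for (i in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      y <- signal::resample(ts$data[i, c, ], p = frac[1], q = frac[2])
      out_data[i, c, ] <- y[seq_len(t_new)]
    }
  }
  eeg_trialset(out_data, ts$labels, target_rate,
               subject_id = ts$subject_id, channel_names = ts$channel_names)
}

# Smallest integer p/q approximation of a rate ratio (exact for the rational
# ratios arising from integer sampling rates).
ratio_integers <- function(r, max_den = 10000L) {
  for (q in seq_len(max_den)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("sampling-rate ratio is not rational within tolerance", call. = FALSE)
}

#' Fit per-channel z-score statistics on a training split
#'
#' Mean and standard deviation per channel, pooled over all trials and
#' timepoints of the (training) set; the standard deviation uses the
#' population divisor. Statistics must be estimated on the training split
#' only and then applied to held-out data — fitting never sees test trials.
#'
#' @param train An [eeg_trialset()] (the training split).
#' @param eps Floor applied to degenerate (constant-channel) standard
#'   deviations so the transform stays finite.
#' @return A `zscore_stats` list with numeric vectors `mean` and `sd`.
#' @export
zscore_fit <- function(train, eps = 1e-8) {
  d <- dim(train$data)
  if (d[1] * d[3] < 2L) stop("need at least 2 samples per channel to fit z-score stats", call. = FALSE)
  mu <- numeric(d[2]); sdev <- numeric(d[2])
  for (c in seq_len(d[2])) {
    v <- as.vector(train$data[, c, ])
    mu[c] <- mean(v)
    s <- sqrt(mean((v - mu[c])^2))
    if (!is.finite(s) || s < eps) {
      warning("channel ", c, " is (near-)constant; std floored at ", eps, call. = FALSE)
      s <- eps
    }
    sdev[c] <- s
  }
  structure(list(mean = mu, sd = sdev), class = "zscore_stats")
}

#' Apply z-score statistics to a trial set
#'
#' @param ts An [eeg_trialset()].
#' @param stats A `zscore_stats` object from [zscore_fit()].
#' @return The standardised `eeg_trialset`.
#' @export
zscore_apply <- function(ts, stats) {
  if (length(stats$mean) != n_channels(ts)) {
    stop("z-score stats were fit on ", length(stats$mean),
         " channels but the trial set has ", n_channels(ts), call. = FALSE)
  }
  out <- ts
  for (c in seq_len(n_channels(ts))) {
    out$data[, c, ] <- (ts$data[, c, ] - stats$mean[c]) / stats$sd[c]
  }
  out
}

#' Run the full preprocessing chain
#'
#' Re-reference, band-pass, notch, then downsample, in that order (z-scoring
#' is deliberately excluded: its statistics are fold-dependent and are fitted
#' inside the cross-validation loop).
#'
#' @param ts An [eeg_trialset()].
#' @param config A [preprocess_config()].
#' @return The conditioned `eeg_trialset`.
#' @export
preprocess <- function(ts, config = preprocess_config()) {
  out <- rereference(ts, config$reference_channels)
  out <- bandpass_filter(out, config$bandpass_low, config$bandpass_high,
                         config$filter_order)
  if (!is.null(config$notch_freq)) out <- notch_filter(out, config$notch_freq)
  if (!is.null(config$target_rate) && config$target_rate != out$sampling_rate) {
    out <- downsample(out, config$target_rate)
  }
  out
}
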