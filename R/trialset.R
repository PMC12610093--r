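#' Labelled multichannel EEG trial set
#'
#' The universal data currency of the package: a `trials x channels x time`
#' numeric array with one class label per trial and sampling metadata.
#' Every pipeline stage (simulation, preprocessing, training, evaluation)
#' consumes and returns this container.
#'
#' @param data Numeric array, `trials x channels x timepoints`, microvolt
#'   scale. All entries must be finite.
#' @param labels Integer vector, one class index per trial, values in `1..m`.
#' @param sampling_rate Sampling rate in Hz (positive scalar).
#' @param subject_id Optional per-trial subject identifier (length 1 or one
#'   per trial); required only for leave-one-subject-out splits.
#' @param channel_names Optional character vector of channel names.
#'
#' @return An object of class `eeg_trialset`: a list with elements `data`,
#'   `labels`, `sampling_rate`, `subject_id`, `channel_names`.
#' @examples
#' x <- array(rnorm(4 * 2 * 32), dim = c(4, 2, 32))
#' ts <- eeg_trialset(x, labels = c(1, 1, 2, 2), sampling_rate = 128)
#' n_trials(ts)
#' @export
eeg_trialset <- function(data, labels, sampling_rate,
                         subject_id = NULL, channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (trials x channels x timepoints)", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("`data` contains non-finite entries", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (dim(data)[1L] != length(labels)) {
    stop("trials dimension of `data` (", dim(data)[1L],
         ") does not match length of `labels` (", length(labels), ")",
         call. = FALSE)
  }
  if (any(labels < 1L)) stop("`labels` must be positive class indices", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive scalar (Hz)", call. = FALSE)
  }
  if (!is.null(subject_id)) {
    if (length(subject_id) == 1L) subject_id <- rep(subject_id, length(labels))
    if (length(subject_id) != length(labels)) {
      stop("`subject_id` must have length 1 or one entry per trial", call. = FALSE)
    }
    subject_id <- as.character(subject_id)
  }
  if (!is.null(channel_names) && length(channel_names) != dim(data)[2L]) {
    stop("`channel_names` must have one entry per channel", call. = FALSE)
  }
  structure(
    list(data = data, labels = labels, sampling_rate = as.numeric(sampling_rate),
         subject_id = subject_id, channel_names = channel_names),
    class = "eeg_trialset"
  )
}

#' @export
print.eeg_trialset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_trialset> %d trials x %d channels x %d timepoints @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  tab <- table(x$labels)
  cat("  classes:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$subject_id)) {
    cat("  subjects:", paste(unique(x$subject_id), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname eeg_trialset
#' @param ts An `eeg_trialset`.
#' @export
n_trials <- function(ts) dim(ts$data)[1L]

#' @rdname eeg_trialset
#' @export
n_channels <- function(ts) dim(ts$data)[2L]

#' @rdname eeg_trialset
#' @export
n_timepoints <- function(ts) dim(ts$data)[3L]

#' Subset trials of a trial set
#'
#' @param ts An `eeg_trialset`.
#' @param idx Trial indices to keep.
#' @return An `eeg_trialset` with the selected trials, metadata preserved.
#' @export
subset_trials <- function(ts, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > n_trials(ts))) stop("trial index out of range", call. = FALSE)
  eeg_trialset(ts$data[idx, , , drop = FALSE], ts$labels[idx], ts$sampling_rate,
               subject_id = if (is.null(ts$subject_id)) NULL else ts$subject_id[idx],
               channel_names = ts$channel_names)
}

#' Extract one trial as a channels x time matrix
#'
#' @param ts An `eeg_trialset`.
#' @param i Trial index.
#' @return A `channels x timepoints` numeric matrix.
#' @export
trial_matrix <- function(ts, i) {
  m <- ts$data[i, , ]
  dim(m) <- dim(ts$data)[2:3]
  m
}

#' Concatenate trial sets along the trial axis
#'
#' All sets must share channel count, timepoint count and sampling rate.
#' Useful for assembling multi-subject sets for leave-one-subject-out
#' evaluation.
#'
#' @param ... `eeg_trialset` objects.
#' @return One combined `eeg_trialset`; `subject_id` is kept when every
#'   input carries one.
#' @export
concat_trialsets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L)
  d2 <- vapply(sets, n_channels, integer(1))
  d3 <- vapply(sets, n_timepoints, integer(1))
  fs <- vapply(sets, function(s) s$sampling_rate, numeric(1))
  if (length(unique(d2)) != 1L || length(unique(d3)) != 1L ||
      length(unique(fs)) != 1L) {
    stop("trial sets differ in geometry or sampling rate", call. = FALSE)
  }
  n_total <- sum(vapply(sets, n_trials, integer(1)))
  data <- array(0, dim = c(n_total, d2[1], d3[1]))
  at <- 0L
  for (s in sets) {
    data[at + seq_len(n_trials(s)), , ] <- s$data
    at <- at + n_trials(s)
  }
  subj <- lapply(sets, `[[`, "subject_id")
  eeg_trialset(data, unlist(lapply(sets, `[[`, "labels")), fs[1],
               subject_id = if (any(vapply(subj, is.null, logical(1)))) NULL
                            else unlist(subj),
               channel_names = sets[[1]]$channel_names)
}

#' Permute trial labels (null control)
#'
#' Returns the same recordings with the label vector uniformly permuted,
#' preserving class counts. Used as a chance-level control: a decoder trained
#' on permuted labels should score at `1/m` on held-out data.
#'
#' @param ts An `eeg_trialset`.
#' @param seed Integer seed; the permutation is reproducible.
#' @return An `eeg_trialset` with identical `data` and permuted `labels`.
#' @export
permute_labels <- function(ts, seed) {
  perm <- with_local_seed(seed, sample.int(n_trials(ts)))
  out <- ts
  out$labels <- ts$labels[perm]
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Read and write trial sets as plain-text containers
#'
#' A trial set is stored as a single tab-separated file: a `#`-prefixed JSON
#' header line carrying dimensions, sampling rate, labels, subject ids and
#' channel names, followed by one row per `(trial, channel)` pair holding the
#' full-precision time series. The round trip is lossless.
#'
#' @param ts An `eeg_trialset`.
#' @param path File path to write to / read from.
#' @return `write_trialset` returns `path` invisibly; `read_trialset` returns
#'   an `eeg_trialset`.
#' @export
write_trialset <- function(ts, path) {
  d <- dim(ts$data)
  header <- jsonlite::toJSON(
    list(n_trials = d[1], n_channels = d[2], n_timepoints = d[3],
         sampling_rate = ts$sampling_rate,
         labels = ts$labels,
         subject_id = ts$subject_id,
         channel_names = ts$channel_names),
    auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", header), con)
  # rows ordered trial-major, channel-minor
  flat <- matrix(aperm(ts$data, c(3L, 2L, 1L)), nrow = d[1] * d[2], byrow = TRUE)
  utils::write.table(format(flat, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trialset
#' @export
read_trialset <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#")) {
    stop("malformed trial-set container: missing JSON header line", call. = FALSE)
  }
  hdr <- jsonlite::fromJSON(sub("^#", "", first))
  for (field in c("n_trials", "n_channels", "n_timepoints", "sampling_rate", "labels")) {
    if (is.null(hdr[[field]])) {
      stop("malformed trial-set container: header field `", field, "` missing",
           call. = FALSE)
    }
  }
  flat <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L,
                                      colClasses = "numeric"))
  if (nrow(flat) != hdr$n_trials * hdr$n_channels || ncol(flat) != hdr$n_timepoints) {
    stop("malformed trial-set container: body shape does not match header",
         call. = FALSE)
  }
  data <- aperm(array(t(flat), dim = c(hdr$n_timepoints, hdr$n_channels, hdr$n_trials)),
                c(3L, 2L, 1L))
  eeg_trialset(data, hdr$labels, hdr$sampling_rate,
               subject_id = hdr$subject_id, channel_names = hdr$channel_names)
}
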