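#' Training configuration
#'
#' Adam optimisation with a stepped learning-rate schedule: the rate is
#' multiplied by `lr_gamma` every `lr_step` epochs
#' (`lr(e) = learning_rate * lr_gamma^floor(e / lr_step)` with `e` counted
#' from 0).
#'
#' @param epochs Number of passes over the training set (default 200).
#' @param learning_rate Base Adam learning rate (default 1e-3).
#' @param lr_step Epochs between learning-rate drops (default 50).
#' @param lr_gamma Multiplicative drop factor (default 0.5).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer seed controlling shuffling and dropout; a fixed seed
#'   reproduces training bit-identically.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 200L, learning_rate = 1e-3, lr_step = 50L,
                         lr_gamma = 0.5, batch_size = 32L, seed = 1L) {
  stopifnot(epochs >= 1, learning_rate > 0, lr_step >= 1,
            lr_gamma > 0, lr_gamma <= 1, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 lr_step = as.integer(lr_step), lr_gamma = lr_gamma,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate in effect at a given epoch
#'
#' @param tc A [train_config()].
#' @param epoch Epoch index counted from 0 (vectorised).
#' @return `learning_rate * lr_gamma^floor(epoch / lr_step)`.
#' @examples
#' lr_schedule(train_config(learning_rate = 1e-3), c(0, 49, 50, 100))
#' @export
lr_schedule <- function(tc, epoch) {
  tc$learning_rate * tc$lr_gamma^(epoch %/% tc$lr_step)
}

#' Mean cross-entropy loss
#'
#' Mean over the batch of the negative log softmax-probability of the true
#' class.
#'
#' @param logits Numeric `batch x m` matrix (a single trial may be given as
#'   a vector).
#' @param labels Integer class labels in `1..m`.
#' @return Non-negative scalar loss.
#' @examples
#' cross_entropy_loss(matrix(0, 1, 4), 1)  # log(4)
#' @export
cross_entropy_loss <- function(logits, labels) {
  if (is.vector(logits)) logits <- matrix(logits, nrow = 1L)
  labels <- as.integer(labels)
  if (nrow(logits) != length(labels)) stop("batch sizes of logits and labels differ", call. = FALSE)
  if (any(labels < 1L | labels > ncol(logits))) {
    stop("labels out of range 1..", ncol(logits), call. = FALSE)
  }
  p <- softmax_rows(logits)
  -mean(log(p[cbind(seq_along(labels), labels)]))
}

trialset_cube <- function(ts) {
  aperm(ts$data, c(2L, 3L, 1L))  # channels x time x trials for the core
}

#' Train a coupled cross-attention network
#'
#' Seeded, shuffled mini-batch Adam optimisation of the cross-entropy loss,
#' with the stepped learning-rate schedule, dropout active in the classifier
#' head, and batch-norm statistics accumulated into the model's running
#' state. Training is deterministic given the seed.
#'
#' The training set is expected to be preprocessed and z-scored (with
#' statistics fitted on this same training split; see [zscore_fit()]).
#'
#' @param model A `cca_net` from [build_model()].
#' @param train An [eeg_trialset()] matching the model's input geometry.
#' @param tc A [train_config()].
#' @return List with `model` (trained) and `history`, a tibble with one row
#'   per epoch: `epoch`, `loss` (mean training loss), `accuracy`
#'   (training-mode accuracy) and `lr`.
#' @export
train_model <- function(model, train, tc = train_config()) {
  cfg <- model$config
  if (n_trials(train) == 0L) stop("empty training set", call. = FALSE)
  if (n_channels(train) != cfg$channels || n_timepoints(train) != cfg$timepoints) {
    stop("trial set geometry (", n_channels(train), " x ", n_timepoints(train),
         ") does not match the model configuration (", cfg$channels, " x ",
         cfg$timepoints, ")", call. = FALSE)
  }
  if (max(train$labels) > cfg$n_classes) {
    stop("labels exceed the configured number of classes", call. = FALSE)
  }
  res <- cpp_train(model$theta, model$state, unclass(cfg),
                   trialset_cube(train), train$labels,
                   tc$epochs, tc$learning_rate, tc$lr_step, tc$lr_gamma,
                   tc$batch_size, tc$seed)
  out <- model
  out$theta <- as.numeric(res$theta)
  out$state <- as.numeric(res$state)
  history <- tibble::tibble(
    epoch = seq_len(tc$epochs) - 1L,
    loss = res$history[, 1],
    accuracy = res$history[, 2],
    lr = res$history[, 3]
  )
  class(history) <- c("training_history", class(history))
  list(model = out, history = history)
}

#' Predict classes or logits for a trial set
#'
#' Evaluation-mode forward pass through the compiled core (running
#' batch-norm statistics, no dropout); deterministic on repeated calls.
#'
#' @param object A trained `cca_net`.
#' @param newdata An [eeg_trialset()] (labels may be dummy).
#' @param type `"class"` (default), `"logits"` or `"prob"`.
#' @param ... Unused.
#' @return Integer labels, a logits matrix, or a probability matrix
#'   (`trials x m`).
#' @export
predict.cca_net <- function(object, newdata, type = c("class", "logits", "prob"), ...) {
  type <- match.arg(type)
  cfg <- object$config
  if (n_channels(newdata) != cfg$channels || n_timepoints(newdata) != cfg$timepoints) {
    stop("trial set geometry does not match the model configuration", call. = FALSE)
  }
  logits <- cpp_predict(object$theta, object$state, unclass(cfg),
                        trialset_cube(newdata))
  switch(type,
         logits = logits,
         prob = softmax_rows(logits),
         class = apply(logits, 1L, argmax_first))
}

#' Per-trial prediction table
#'
#' @param model A trained `cca_net`.
#' @param ts An [eeg_trialset()].
#' @return Tibble with `trial`, `true_label`, `predicted_label` and one
#'   `logit_<c>` column per class.
#' @export
prediction_table <- function(model, ts) {
  logits <- predict(model, ts, type = "logits")
  pred <- apply(logits, 1L, argmax_first)
  out <- tibble::tibble(trial = seq_len(n_trials(ts)),
                        true_label = ts$labels,
                        predicted_label = as.integer(pred))
  colnames(logits) <- paste0("logit_", seq_len(ncol(logits)))
  tibble::as_tibble(cbind(out, tibble::as_tibble(logits)))
}
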