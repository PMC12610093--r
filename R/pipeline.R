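# z-score fitting with an explicit leakage guard: statistics may only be
# functions of the training indices.
guarded_zscore_fit <- function(ts, fit_idx, test_idx) {
  if (length(intersect(fit_idx, test_idx)) > 0L) {
    stop("leakage guard: test indices reached z-score fitting", call. = FALSE)
  }
  zscore_fit(subset_trials(ts, fit_idx))
}

#' Cross-validated training and evaluation
#'
#' For every fold of the plan: z-score statistics are fitted on the training
#' split only (a leakage guard refuses overlapping indices), applied to both
#' splits, a fresh model is built and trained, and held-out accuracy,
#' macro F1 and (optionally) channel-dropout robustness are measured.
#' Per-fold model and training seeds are derived from `seed` plus the fold
#' index, so the whole procedure is reproducible.
#'
#' @param ts A preprocessed [eeg_trialset()] (not yet z-scored).
#' @param plan A `fold_plan` from [stratified_kfold()] or [loso_split()].
#' @param model_args Named list of [model_config()] overrides (e.g.
#'   `list(k = 16, fusion = "sum")`); geometry and class count come from the
#'   data.
#' @param tc A [train_config()].
#' @param dropout_fractions Channel-dropout fractions evaluated per fold
#'   (default none).
#' @param seed Base seed for per-fold model initialisation.
#' @return A `metrics_report`: list with `per_fold` (tibble), `mean`, `sd`
#'   (population divisor over folds, percent), `f1` (macro F1 pooled over
#'   all held-out predictions), `confusion` (pooled `m x m` matrix),
#'   `robustness` (named means of the dropout columns) and `scheme`.
#' @export
cross_validate <- function(ts, plan, model_args = list(), tc = train_config(),
                           dropout_fractions = numeric(0), seed = 1L) {
  m <- max(ts$labels)
  per_fold <- vector("list", length(plan$folds))
  confusion <- matrix(0L, m, m)
  true_all <- integer(0); pred_all <- integer(0)
  for (i in seq_along(plan$folds)) {
    f <- plan$folds[[i]]
    stats <- guarded_zscore_fit(ts, f$train, f$test)
    tr <- zscore_apply(subset_trials(ts, f$train), stats)
    te <- zscore_apply(subset_trials(ts, f$test), stats)
    cfg <- do.call(model_config, c(
      list(channels = n_channels(ts), timepoints = n_timepoints(ts),
           sampling_rate = ts$sampling_rate, n_classes = m),
      model_args))
    fold_tc <- tc
    fold_tc$seed <- tc$seed + i
    fit <- train_model(build_model(cfg, seed = seed + i), tr, fold_tc)
    row <- evaluate_model(fit$model, te, dropout_fractions = dropout_fractions,
                          seed = seed + i)
    confusion <- confusion + attr(row, "confusion")
    pred <- predict(fit$model, te, type = "class")
    true_all <- c(true_all, te$labels); pred_all <- c(pred_all, pred)
    per_fold[[i]] <- tibble::tibble(fold = i, row)
  }
  per_fold <- do.call(rbind, per_fold)
  summ <- accuracy_summary(per_fold$accuracy)
  rob_cols <- grep("^accuracy_drop", names(per_fold), value = TRUE)
  structure(list(per_fold = per_fold, mean = summ$mean, sd = summ$sd,
                 f1 = confusion_and_f1(true_all, pred_all, m)$f1,
                 confusion = confusion,
                 robustness = vapply(rob_cols, function(cl) mean(per_fold[[cl]]),
                                     numeric(1)),
                 scheme = plan$scheme),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s, %d folds\n", x$scheme, nrow(x$per_fold)))
  cat(sprintf("  accuracy: %.2f +/- %.2f %%   macro F1: %.4f\n", x$mean, x$sd, x$f1))
  if (length(x$robustness)) {
    cat("  robustness:", paste(sprintf("%s = %.2f%%", names(x$robustness),
                                       x$robustness), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run manifest: one self-contained experiment description
#'
#' Bundles every stage configuration needed to reproduce a run from scratch:
#' either a synthetic-data configuration or a path to a stored trial set,
#' the preprocessing chain, model overrides, training configuration and the
#' evaluation scheme. [run_pipeline()] executes it deterministically.
#'
#' @param synth A [synth_config()], or `NULL` when `data_path` is given.
#' @param data_path Path to a trial-set container ([write_trialset()]), or
#'   `NULL` when `synth` is given.
#' @param preprocess A [preprocess_config()], or `NULL` to skip conditioning.
#' @param model Named list of [model_config()] overrides.
#' @param train A [train_config()].
#' @param scheme `"stratified_kfold"` or `"loso"`.
#' @param n_folds Fold count for the stratified scheme.
#' @param seed Base seed for fold assignment and per-fold initialisation.
#' @param dropout_fractions Channel-dropout fractions evaluated per fold.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(synth = NULL, data_path = NULL, preprocess = NULL,
                         model = list(), train = train_config(),
                         scheme = c("stratified_kfold", "loso"), n_folds = 5L,
                         seed = 1L, dropout_fractions = numeric(0)) {
  scheme <- match.arg(scheme)
  if (is.null(synth) && is.null(data_path)) {
    stop("a manifest needs either a synthetic-data config or a data path", call. = FALSE)
  }
  structure(list(synth = synth, data_path = data_path, preprocess = preprocess,
                 model = model, train = train, scheme = scheme,
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 dropout_fractions = dropout_fractions,
                 version = as.character(utils::packageVersion("eegcca"))),
            class = "run_manifest")
}

#' Execute a run manifest end to end
#'
#' Simulate (or load), precondition, split, train and evaluate, in that
#' order. Z-score statistics are fitted inside each training fold only.
#' Re-running the same manifest reproduces the metrics exactly.
#'
#' @param manifest A [run_manifest()].
#' @return A `metrics_report` (see [cross_validate()]); the manifest is
#'   attached as attribute `"manifest"`.
#' @export
run_pipeline <- function(manifest) {
  ts <- if (!is.null(manifest$synth)) {
    generate_trialset(manifest$synth)
  } else {
    read_trialset(manifest$data_path)
  }
  if (!is.null(manifest$preprocess)) ts <- preprocess(ts, manifest$preprocess)
  plan <- if (manifest$scheme == "loso") {
    if (is.null(ts$subject_id)) stop("loso scheme requires per-trial subject ids", call. = FALSE)
    loso_split(ts$subject_id)
  } else {
    stratified_kfold(ts$labels, manifest$n_folds, seed = manifest$seed)
  }
  report <- cross_validate(ts, plan, model_args = manifest$model,
                           tc = manifest$train,
                           dropout_fractions = manifest$dropout_fractions,
                           seed = manifest$seed)
  attr(report, "manifest") <- manifest
  report
}

#' Ablation grid over variants and fusion strategies
#'
#' Builds, trains and cross-validates every requested
#' `variant x fusion` combination on the same data and fold plan.
#'
#' @param ts A preprocessed [eeg_trialset()].
#' @param variants Character vector of model variants.
#' @param fusions Character vector of fusion strategies.
#' @param model_args Shared [model_config()] overrides applied to every cell.
#' @param tc A [train_config()].
#' @param n_folds Fold count.
#' @param seed Base seed (same folds for every cell).
#' @return Tibble with one row per combination: `variant`, `fusion`,
#'   `mean_accuracy`, `sd_accuracy`, `f1`, `n_parameters`.
#' @export
run_ablation <- function(ts, variants = c("full", "no_lfem", "no_gfem"),
                         fusions = c("cca", "sum", "cat", "atten"),
                         model_args = list(), tc = train_config(),
                         n_folds = 5L, seed = 1L) {
  plan <- stratified_kfold(ts$labels, n_folds, seed = seed)
  grid <- expand.grid(variant = variants, fusion = fusions,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    args <- c(model_args, list(variant = grid$variant[i], fusion = grid$fusion[i]))
    rep_ <- cross_validate(ts, plan, model_args = args, tc = tc, seed = seed)
    cfg <- do.call(model_config, c(
      list(channels = n_channels(ts), timepoints = n_timepoints(ts),
           sampling_rate = ts$sampling_rate, n_classes = max(ts$labels)),
      args))
    tibble::tibble(variant = grid$variant[i], fusion = grid$fusion[i],
                   mean_accuracy = rep_$mean, sd_accuracy = rep_$sd,
                   f1 = rep_$f1,
                   n_parameters = count_parameters(build_model(cfg, seed = 1L)))
  })
  do.call(rbind, rows)
}

#' Compare fusion strategies over several seeds
#'
#' Trains the same architecture with different fusion strategies over a set
#' of seeds (fresh fold assignment, initialisation and training order per
#' seed) and reports the per-seed mean accuracies — the protocol behind the
#' directional claim that coupled cross-attention fusion is at least as good
#' as its static baselines.
#'
#' @param ts A preprocessed [eeg_trialset()].
#' @param strategies Fusion strategies to compare (default `c("cca", "sum")`).
#' @param seeds Integer seeds.
#' @param model_args Shared [model_config()] overrides.
#' @param tc A [train_config()].
#' @param n_folds Fold count per run.
#' @return Tibble with `seed`, `fusion`, `mean_accuracy`.
#' @export
compare_fusion <- function(ts, strategies = c("cca", "sum"), seeds = 1:3,
                           model_args = list(), tc = train_config(),
                           n_folds = 5L) {
  rows <- list()
  for (s in seeds) {
    plan <- stratified_kfold(ts$labels, n_folds, seed = s)
    for (f in strategies) {
      tc_s <- tc; tc_s$seed <- s
      rep_ <- cross_validate(ts, plan, model_args = c(model_args, list(fusion = f)),
                             tc = tc_s, seed = s)
      rows[[length(rows) + 1L]] <- tibble::tibble(seed = s, fusion = f,
                                                  mean_accuracy = rep_$mean)
    }
  }
  do.call(rbind, rows)
}
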