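#' Global feature extraction: multi-head self-attention
#'
#' Projects the fused sequence to query, key and value (each `k -> k`, with
#' bias), splits the feature axis into `h` heads of width `k/h`, applies
#' scaled dot-product attention independently per head (scaling by
#' `sqrt(k/h)`), concatenates the head outputs back to width `k`, and
#' applies a final `k -> k` output projection. With no positional encoding,
#' jointly permuting the input positions permutes the output rows
#' identically.
#'
#' @param f Fused `feature_seq` (`seq_len x k`).
#' @param model A `cca_net` whose variant includes the global stage, or a
#'   list with fields `Wgq, bgq, Wgk, bgk, Wgv, bgv, Wgo, bgo, h`.
#' @return A `feature_seq` with role `"global"` (`seq_len x k`).
#' @export
multi_head_self_attention <- function(f, model) {
  if (inherits(model, "cca_net")) {
    if (model$config$variant == "no_gfem") {
      stop("model variant has no global attention stage", call. = FALSE)
    }
    p <- net_params(model)
    p$h <- model$config$h
  } else p <- model
  k <- ncol(f)
  h <- p$h
  if (k %% h != 0L) stop("feature width ", k, " not divisible by head count ", h, call. = FALSE)
  hw <- k %/% h
  Q <- project_seq(f, p$Wgq, p$bgq)
  K <- project_seq(f, p$Wgk, p$bgk)
  V <- project_seq(f, p$Wgv, p$bgv)
  out <- matrix(0, nrow(f), k)
  for (l in seq_len(h)) {
    cols <- ((l - 1L) * hw + 1L):(l * hw)
    out[, cols] <- scaled_dot_product_attention(Q[, cols, drop = FALSE],
                                                K[, cols, drop = FALSE],
                                                V[, cols, drop = FALSE],
                                                dk = hw)
  }
  feature_seq(out %*% p$Wgo + rep_row(p$bgo, nrow(f)), "global")
}

#' Classification head
#'
#' Flattens the global feature sequence (column-major `seq_len x k`), applies
#' a hidden affine layer with ELU, and a final affine map to the class
#' logits. The predicted label is the argmax of the logits, taking the
#' lowest index on ties. Dropout is active only during training; this
#' evaluation-mode path is deterministic.
#'
#' @param fg Global `feature_seq` (`seq_len x k`), or any matrix.
#' @param model A `cca_net` (its `W_fc1/b_fc1/W_fc2/b_fc2` are used).
#' @return List with `logits` (length `m`) and `predicted_label` (in `1..m`).
#' @export
classify <- function(fg, model) {
  p <- net_params(model)
  z <- as.vector(unclass(fg))
  if (length(z) != nrow(p$W_fc1)) {
    stop("flattened feature length ", length(z), " does not match classifier input ",
         nrow(p$W_fc1), call. = FALSE)
  }
  a <- elu(drop(z %*% p$W_fc1) + as.vector(p$b_fc1))
  logits <- drop(a %*% p$W_fc2) + as.vector(p$b_fc2)
  list(logits = logits, predicted_label = argmax_first(logits))
}

# argmax with lowest-index tie-break
argmax_first <- function(x) which.max(x)

#' Reference forward pass for a single trial
#'
#' Composes the R-level module operations (evaluation mode: running
#' batch-norm statistics, no dropout) into the full network. This is the
#' readable reference implementation; batch training and prediction run
#' through the compiled core, which is cross-checked against this function
#' in the test suite.
#'
#' @param model A `cca_net`.
#' @param x A `channels x timepoints` trial matrix.
#' @return List with `logits` and `predicted_label`.
#' @export
forward_trial <- function(model, x) {
  cfg <- model$config
  if (cfg$variant == "no_lfem") {
    streams <- no_lfem_streams(x, model)
    ft <- streams$temporal; fs <- streams$spatial
  } else {
    ft <- temporal_pathway(x, model)
    fs <- spatial_pathway(x, model)
  }
  fused <- if (cfg$fusion == "cca") {
    fts <- cross_attention_ts(ft, fs, attention_projections(model, "ts"))
    fst <- cross_attention_st(fs, ft, attention_projections(model, "st"))
    fuse(fts, fst, fusion_weights(model))
  } else {
    p <- net_params(model)
    fusion_baseline(ft, fs, cfg$fusion,
                    weights = list(Wcat = p$Wcat, bcat = p$bcat,
                                   Wat = p$Wat, bat = p$bat))
  }
  top <- if (cfg$variant == "no_gfem") fused else multi_head_self_attention(fused, model)
  classify(top, model)
}
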