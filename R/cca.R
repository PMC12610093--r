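#' Attention projection maps of one cross-attention direction
#'
#' Extracts the query/key/value affine maps (each `k -> k`, with bias) for
#' one direction of the coupled cross-attention stage.
#'
#' @param model A `cca_net` with `fusion = "cca"`.
#' @param direction `"ts"` (temporal queries attend to spatial keys/values)
#'   or `"st"` (the reverse).
#' @return List with `Wq`, `bq`, `Wk`, `bk`, `Wv`, `bv` and the scaling
#'   width `dk = k`.
#' @export
attention_projections <- function(model, direction = c("ts", "st")) {
  direction <- match.arg(direction)
  if (model$config$fusion != "cca") {
    stop("attention projections exist only for fusion = \"cca\"", call. = FALSE)
  }
  p <- net_params(model)
  g <- function(nm) p[[paste0(nm, "_", direction)]]
  list(Wq = g("Wq"), bq = g("bq"), Wk = g("Wk"), bk = g("bk"),
       Wv = g("Wv"), bv = g("bv"), dk = model$config$k)
}

project_seq <- function(f, W, b) {
  unclass(f) %*% W + rep_row(b, nrow(f))
}

#' Cross-attention: temporal queries over spatial keys/values
#'
#' `fts = Atten(proj_q(ft), proj_k(fs), proj_v(fs))` — the temporal stream
#' queries the spatial stream, selecting the spatial components most
#' relevant at each sequence position.
#'
#' @param ft Temporal `feature_seq` (`seq_len x k`).
#' @param fs Spatial `feature_seq` (`seq_len x k`).
#' @param proj Projections from [attention_projections()] (or any list with
#'   the same fields, e.g. identity maps in tests).
#' @return A `seq_len x k` matrix (`feature_seq`, role `"temporal"`).
#' @export
cross_attention_ts <- function(ft, fs, proj) {
  check_pair(ft, fs)
  out <- scaled_dot_product_attention(project_seq(ft, proj$Wq, proj$bq),
                                      project_seq(fs, proj$Wk, proj$bk),
                                      project_seq(fs, proj$Wv, proj$bv),
                                      dk = proj$dk)
  feature_seq(out, "temporal")
}

#' Cross-attention: spatial queries over temporal keys/values
#'
#' `fst = Atten(proj_q(fs), proj_k(ft), proj_v(ft))` — the reverse direction,
#' letting spatial features select the most informative temporal dynamics.
#'
#' @inheritParams cross_attention_ts
#' @return A `seq_len x k` matrix (`feature_seq`, role `"spatial"`).
#' @export
cross_attention_st <- function(fs, ft, proj) {
  check_pair(fs, ft)
  out <- scaled_dot_product_attention(project_seq(fs, proj$Wq, proj$bq),
                                      project_seq(ft, proj$Wk, proj$bk),
                                      project_seq(ft, proj$Wv, proj$bv),
                                      dk = proj$dk)
  feature_seq(out, "spatial")
}

check_pair <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("the two feature sequences must have identical shape; got ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"),
         call. = FALSE)
  }
  invisible(NULL)
}

#' Fuse the two cross-attention outputs
#'
#' `ffusion = LN(alpha * fts + beta * fst)`: a weighted sum with learnable
#' unconstrained scalar weights, layer-normalised over the feature axis.
#'
#' @param fts,fst The two cross-attention outputs (`seq_len x k`).
#' @param w Fusion weights: list with scalars `alpha`, `beta` and layer-norm
#'   vectors `gain`, `shift` (length `k`). Defaults to the symmetric start
#'   `alpha = beta = 1`, unit gain, zero shift.
#' @return A `feature_seq` with role `"fused"`.
#' @export
fuse <- function(fts, fst, w = NULL) {
  check_pair(fts, fst)
  k <- ncol(fts)
  w <- w %||% list(alpha = 1, beta = 1, gain = rep(1, k), shift = rep(0, k))
  pre <- w$alpha * unclass(fts) + w$beta * unclass(fst)
  feature_seq(layer_norm(pre, w$gain, w$shift), "fused")
}

fusion_weights <- function(model) {
  p <- net_params(model)
  list(alpha = as.numeric(p$alpha), beta = as.numeric(p$beta),
       gain = as.vector(p$ln_gain), shift = as.vector(p$ln_shift))
}

#' Baseline fusion strategies
#'
#' The three conventional alternatives to coupled cross-attention used in
#' the fusion ablation: plain summation, feature-axis concatenation followed
#' by a linear map back to width `k` (so downstream shapes are unchanged),
#' and "standard attention" — two scalar weights obtained by a linear
#' projection of the position-pooled pair, softmax-normalised, applied as a
#' convex combination of the two streams.
#'
#' @param ft,fs The temporal and spatial feature sequences (`seq_len x k`).
#' @param strategy One of `"sum"`, `"cat"`, `"atten"`.
#' @param weights Strategy parameters: `cat` needs `Wcat` (`2k x k`) and
#'   `bcat`; `atten` needs `Wat` (`2k x 2`) and `bat`; `sum` needs none.
#' @param return_weights For `"atten"`, also return the two softmax weights.
#' @return A `feature_seq` with role `"fused"` (plus `weights` when
#'   requested).
#' @export
fusion_baseline <- function(ft, fs, strategy, weights = NULL,
                            return_weights = FALSE) {
  if (!strategy %in% c("sum", "cat", "atten")) {
    stop("unknown fusion strategy \"", strategy,
         "\"; valid options are: sum, cat, atten (or cca via the full model)",
         call. = FALSE)
  }
  check_pair(ft, fs)
  k <- ncol(ft)
  out <- switch(strategy,
    sum = unclass(ft) + unclass(fs),
    cat = {
      if (is.null(weights$Wcat)) stop("`cat` fusion requires Wcat/bcat weights", call. = FALSE)
      cbind(unclass(ft), unclass(fs)) %*% weights$Wcat +
        rep_row(weights$bcat, nrow(ft))
    },
    atten = {
      if (is.null(weights$Wat)) stop("`atten` fusion requires Wat/bat weights", call. = FALSE)
      pooled <- c(colMeans(ft), colMeans(fs))
      wl <- drop(pooled %*% weights$Wat) + as.vector(weights$bat)
      ww <- drop(softmax_rows(matrix(wl, 1L)))
      ww[1] * unclass(ft) + ww[2] * unclass(fs)
    })
  fused <- feature_seq(out, "fused")
  if (return_weights && strategy == "atten") {
    pooled <- c(colMeans(ft), colMeans(fs))
    wl <- drop(pooled %*% weights$Wat) + as.vector(weights$bat)
    list(fused = fused, weights = drop(softmax_rows(matrix(wl, 1L))))
  } else fused
}
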