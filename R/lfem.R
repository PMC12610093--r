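# Reshape a stored (c_in*kh*kw x c_out) weight matrix into the 4-d kernel
# array (c_out, c_in, kh, kw) used by conv2d_valid.
conv_weight_array <- function(wmat, c_in, kh, kw) {
  c_out <- ncol(wmat)
  aperm(array(wmat, dim = c(c_in, kh, kw, c_out)), c(4L, 1L, 2L, 3L))
}

#' Local feature extraction: temporal-first convolutional pathway
#'
#' Applies, to one `channels x time` trial plane: a temporal convolution
#' (kernel `1 x floor(fs/10)`, 1 input map to `k` maps), then a spatial
#' convolution (kernel `floor(ch/2) x 1`, `k` to `k` maps), batch
#' normalisation over the `k` feature maps, ELU, and `(4, 4)` average
#' pooling with stride equal to the window. The pooled map is then mapped to
#' a fixed-length `seq_len x k` feature sequence by [to_sequence()]. Both
#' convolutions are valid (no padding), stride 1, bias-free (the batch norm
#' absorbs any bias).
#'
#' Batch statistics are taken from the model's running state (evaluation
#' mode); during training the compiled core uses per-batch statistics.
#'
#' @param x Numeric `channels x timepoints` matrix (one trial).
#' @param model A `cca_net` built with a variant that includes the
#'   convolutional front end.
#' @return A `feature_seq` with role `"temporal"` (`seq_len x k`).
#' @export
temporal_pathway <- function(x, model) {
  cfg <- model$config
  if (cfg$variant == "no_lfem") stop("model variant has no convolutional front end", call. = FALSE)
  p <- net_params(model)
  sh <- lfem_shapes(cfg$channels, cfg$timepoints, cfg$sampling_rate, cfg$k)
  check_plane(x, cfg)
  a <- conv2d_valid(array(x, dim = c(1L, nrow(x), ncol(x))),
                    conv_weight_array(p$conv_t1_w, 1L, 1L, sh$kt))
  a <- conv2d_valid(a, conv_weight_array(p$conv_t2_w, cfg$k, sh$kc, 1L))
  a <- batch_norm_eval(a, p$bn_t_gamma, p$bn_t_beta,
                       model$state[seq_len(cfg$k)],
                       model$state[cfg$k + seq_len(cfg$k)])
  a <- avg_pool2d(elu(a))
  to_sequence(a, cfg$seq_len, role = "temporal")
}

#' Local feature extraction: spatial-first convolutional pathway
#'
#' The mirror of [temporal_pathway()]: spatial convolution
#' (`floor(ch/2) x 1`) first, then temporal convolution (`1 x floor(fs/10)`),
#' batch norm, ELU, `(4, 4)` average pooling, and the map to a
#' `seq_len x k` sequence. For every valid input geometry the output shape
#' equals the temporal pathway's.
#'
#' @inheritParams temporal_pathway
#' @return A `feature_seq` with role `"spatial"`.
#' @export
spatial_pathway <- function(x, model) {
  cfg <- model$config
  if (cfg$variant == "no_lfem") stop("model variant has no convolutional front end", call. = FALSE)
  p <- net_params(model)
  sh <- lfem_shapes(cfg$channels, cfg$timepoints, cfg$sampling_rate, cfg$k)
  check_plane(x, cfg)
  a <- conv2d_valid(array(x, dim = c(1L, nrow(x), ncol(x))),
                    conv_weight_array(p$conv_s1_w, 1L, sh$kc, 1L))
  a <- conv2d_valid(a, conv_weight_array(p$conv_s2_w, cfg$k, 1L, sh$kt))
  a <- batch_norm_eval(a, p$bn_s_gamma, p$bn_s_beta,
                       model$state[2L * cfg$k + seq_len(cfg$k)],
                       model$state[3L * cfg$k + seq_len(cfg$k)])
  a <- avg_pool2d(elu(a))
  to_sequence(a, cfg$seq_len, role = "spatial")
}

check_plane <- function(x, cfg) {
  if (!is.matrix(x) || nrow(x) != cfg$channels || ncol(x) != cfg$timepoints) {
    stop("trial plane must be ", cfg$channels, " x ", cfg$timepoints,
         " (channels x timepoints); got ", nrow(x), " x ", ncol(x), call. = FALSE)
  }
  invisible(x)
}

# The two fixed-pooling streams of the `no_lfem` ablation: the raw plane is
# flattened (time-major for the temporal stream, channel-major for the
# spatial stream), box-resampled to seq_len positions, and widened 1 -> k by
# a learned projection.
no_lfem_streams <- function(x, model) {
  cfg <- model$config
  p <- net_params(model)
  M <- resample_matrix(length(x), cfg$seq_len)
  st <- M %*% as.vector(x)        # column-major ch x t: channel fastest (time-major walk)
  ss <- M %*% as.vector(t(x))     # channel-major walk
  list(temporal = feature_seq(st %*% p$proj_t_w + rep_row(p$proj_t_b, cfg$seq_len), "temporal"),
       spatial = feature_seq(ss %*% p$proj_s_w + rep_row(p$proj_s_b, cfg$seq_len), "spatial"))
}

rep_row <- function(b, n) matrix(rep(as.vector(b), each = n), nrow = n)
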