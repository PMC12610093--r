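`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exponential linear unit
#'
#' `x` for `x >= 0`, `alpha * (exp(x) - 1)` for `x < 0`.
#'
#' @param x Numeric vector/matrix/array.
#' @param alpha ELU scale for the negative branch (default 1).
#' @return Object of the same shape as `x`.
#' @export
elu <- function(x, alpha = 1) {
  ifelse(x >= 0, x, alpha * (exp(x) - 1))
}

#' Row-wise numerically stable softmax
#'
#' Computed with max-subtraction, so the result is invariant to adding a
#' constant to every logit in a row; each output row sums to 1.
#'
#' @param x Numeric matrix of logits.
#' @return Matrix of the same shape with non-negative rows summing to 1.
#' @export
softmax_rows <- function(x) {
  x <- as.matrix(x)
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Valid 2-d convolution (cross-correlation, no flipping, stride 1, no bias).
# x: array (c_in, H, W); w: array (c_out, c_in, kh, kw).
# Returns array (c_out, H - kh + 1, W - kw + 1).
conv2d_valid <- function(x, w) {
  dx <- dim(x); dw <- dim(w)
  if (dx[1] != dw[2]) stop("conv input channels (", dx[1], ") do not match kernel (", dw[2], ")", call. = FALSE)
  H <- dx[2] - dw[3] + 1L
  W <- dx[3] - dw[4] + 1L
  if (H < 1L || W < 1L) {
    stop("kernel (", dw[3], ",", dw[4], ") larger than input plane (",
         dx[2], ",", dx[3], ")", call. = FALSE)
  }
  # im2col: rows index (c_in, u, v), columns index output (i, j)
  col <- matrix(0, dw[2] * dw[3] * dw[4], H * W)
  r <- 1L
  for (v in seq_len(dw[4])) {
    for (u in seq_len(dw[3])) {
      for (cc in seq_len(dw[2])) {
        patch <- x[cc, u:(u + H - 1L), v:(v + W - 1L), drop = FALSE]
        col[r, ] <- as.vector(patch)
        r <- r + 1L
      }
    }
  }
  wm <- matrix(aperm(w, c(2L, 3L, 4L, 1L)), ncol = dw[1])  # (c_in*kh*kw) x c_out
  out <- t(wm) %*% col
  array(out, dim = c(dw[1], H, W))
}

# Average pooling with window = stride = `pool` (floor boundary handling).
# x: array (k, H, W) -> (k, floor(H/ph), floor(W/pw)).
avg_pool2d <- function(x, pool = c(4L, 4L)) {
  d <- dim(x)
  ph <- pool[1]; pw <- pool[2]
  Ho <- d[2] %/% ph; Wo <- d[3] %/% pw
  if (Ho < 1L || Wo < 1L) stop("pooling window larger than feature map", call. = FALSE)
  out <- array(0, dim = c(d[1], Ho, Wo))
  for (i in seq_len(Ho)) {
    for (j in seq_len(Wo)) {
      block <- x[, ((i - 1L) * ph + 1L):(i * ph), ((j - 1L) * pw + 1L):(j * pw), drop = FALSE]
      out[, i, j] <- apply(block, 1L, mean)
    }
  }
  out
}

# Batch-norm in evaluation mode: per-feature-map affine using running stats.
# x: array (k, H, W); all stat vectors length k.
batch_norm_eval <- function(x, gamma, beta, running_mean, running_var, eps = 1e-5) {
  k <- dim(x)[1]
  out <- x
  for (f in seq_len(k)) {
    out[f, , ] <- gamma[f] * (x[f, , ] - running_mean[f]) /
      sqrt(running_var[f] + eps) + beta[f]
  }
  out
}

# Box-average (area-preserving) resampling matrix from n positions to
# seq_len positions. Treats the n inputs as a piecewise-constant function on
# [0, 1]; output s is its average over the s-th of seq_len equal intervals.
# Rows sum to 1; the output mean equals the input mean exactly; identity when
# n == seq_len.
resample_matrix <- function(n, seq_len = 512L) {
  if (n == seq_len) return(diag(n))
  M <- matrix(0, seq_len, n)
  for (s in seq_len(seq_len)) {
    a <- (s - 1) / seq_len; b <- s / seq_len
    j0 <- floor(a * n) + 1L
    j1 <- min(n, ceiling(b * n))
    for (j in j0:j1) {
      lo <- max(a, (j - 1) / n); hi <- min(b, j / n)
      if (hi > lo) M[s, j] <- (hi - lo)
    }
    M[s, ] <- M[s, ] / (b - a)
  }
  M
}

#' Map a convolutional feature map to a fixed-length feature sequence
#'
#' Flattens a `k x H x W` feature map to `H*W` positions (row-major over the
#' plane: position `p = (i-1)*W + j`), then box-average resamples the
#' position axis to exactly `seq_len` positions. The resampling is
#' area-preserving, so the mean over positions is preserved (to float
#' precision), and it reduces to a pure rearrangement when `H*W == seq_len`.
#'
#' @param featmap Numeric array `k x H x W`.
#' @param seq_len Target sequence length (default 512).
#' @param role Role tag for the resulting sequence.
#' @return A `feature_seq`: a `seq_len x k` matrix with a `role` attribute.
#' @export
to_sequence <- function(featmap, seq_len = 512L, role = "temporal") {
  d <- dim(featmap)
  if (length(d) != 3L) stop("`featmap` must be a k x H x W array", call. = FALSE)
  n <- d[2] * d[3]
  # row-major flatten of each map: position p = (i-1)*W + j holds featmap[f, i, j]
  flat <- matrix(aperm(featmap, c(3L, 2L, 1L)), nrow = n)
  seq <- resample_matrix(n, seq_len) %*% flat
  feature_seq(seq, role)
}

#' Feature sequence constructor
#'
#' A `positions x features` matrix representing one trial inside the network,
#' tagged with its role: `temporal` (ft), `spatial` (fs), `fused` (ffusion)
#' or `global` (fg).
#'
#' @param values Numeric `positions x features` matrix.
#' @param role One of `"temporal"`, `"spatial"`, `"fused"`, `"global"`.
#' @return A `feature_seq` object.
#' @export
feature_seq <- function(values, role = c("temporal", "spatial", "fused", "global")) {
  role <- match.arg(role)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("feature sequence contains non-finite entries", call. = FALSE)
  structure(values, role = role, class = c("feature_seq", "matrix", "array"))
}

seq_role <- function(f) attr(f, "role") %||% NA_character_

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(dk)) V` with row-wise softmax; every attention weight
#' row sums to 1.
#'
#' @param Q,K,V Numeric `positions x k` matrices (`K` and `V` share their
#'   position count; `Q` and `K` share feature width).
#' @param dk Query width used in the `1/sqrt(dk)` scaling (defaults to
#'   `ncol(Q)`).
#' @param return_weights If `TRUE`, also return the attention weight matrix.
#' @return The `positions(Q) x ncol(V)` output matrix, or a list
#'   `(output, weights)` when `return_weights = TRUE`.
#' @export
scaled_dot_product_attention <- function(Q, K, V, dk = ncol(Q),
                                         return_weights = FALSE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (!all(is.finite(Q), is.finite(K), is.finite(V))) {
    stop("attention inputs contain non-finite values", call. = FALSE)
  }
  if (ncol(Q) != ncol(K)) stop("Q and K feature widths differ", call. = FALSE)
  if (nrow(K) != nrow(V)) stop("K and V position counts differ", call. = FALSE)
  if (dk <= 0) stop("`dk` must be positive", call. = FALSE)
  W <- softmax_rows(Q %*% t(K) / sqrt(dk))
  out <- W %*% V
  if (return_weights) list(output = out, weights = W) else out
}

#' Layer normalisation over the feature axis
#'
#' Each position (row) is normalised to zero mean and unit variance across
#' its `k` features, then scaled and shifted by the learnable per-feature
#' gain and shift.
#'
#' @param x Numeric `positions x k` matrix.
#' @param gain,shift Numeric vectors of length `k` (defaults: ones / zeros).
#' @param eps Variance floor (default 1e-5).
#' @return Matrix of the same shape.
#' @export
layer_norm <- function(x, gain = rep(1, ncol(x)), shift = rep(0, ncol(x)),
                       eps = 1e-5) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  va <- rowMeans((x - mu)^2)
  xn <- (x - mu) / sqrt(va + eps)
  sweep(sweep(xn, 2L, gain, `*`), 2L, shift, `+`)
}
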