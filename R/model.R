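#' Convolution kernel dimensions from channel count and sampling rate
#'
#' The temporal kernel spans `floor(fs/10)` samples along time; the spatial
#' kernel spans `floor(ch/2)` electrodes. Both use floor division.
#'
#' @param ch Number of EEG channels (>= 2).
#' @param fs Sampling rate in Hz (>= 10).
#' @return List with integer `temporal = c(1, floor(fs/10))` and
#'   `spatial = c(floor(ch/2), 1)` kernel sizes.
#' @examples
#' kernel_dims(128, 256)  # (1, 25) and (64, 1)
#' @export
kernel_dims <- function(ch, fs) {
  if (ch < 2) stop("need at least 2 channels", call. = FALSE)
  if (fs < 10) stop("sampling rate must be >= 10 Hz for a non-empty temporal kernel",
                    call. = FALSE)
  list(temporal = c(1L, as.integer(fs) %/% 10L),
       spatial = c(as.integer(ch) %/% 2L, 1L))
}

#' Model configuration
#'
#' All architecture hyperparameters of the hierarchical coupled
#' cross-attention network, including the ablation switches.
#'
#' @param channels,timepoints,sampling_rate Input trial geometry.
#' @param n_classes Number of target classes `m`.
#' @param k Feature width: output channels of every convolution and the
#'   feature dimension of all attention stages (default 32).
#' @param h Self-attention head count in the global stage (default 4; must
#'   divide `k`).
#' @param seq_len Internal sequence length (default 512).
#' @param fusion Fusion strategy: `"cca"` (bidirectional coupled
#'   cross-attention, the full model) or one of the baselines `"sum"`,
#'   `"cat"`, `"atten"`.
#' @param variant `"full"`, `"no_lfem"` (convolutional front end replaced by
#'   fixed pooling plus a learned width projection per stream) or
#'   `"no_gfem"` (global self-attention stage removed).
#' @param fc_hidden Hidden width of the classifier head (default 256).
#' @param dropout Dropout probability in the classifier head, active only
#'   during training (default 0.3).
#' @return A `model_config` list.
#' @export
model_config <- function(channels, timepoints, sampling_rate, n_classes,
                         k = 32L, h = 4L, seq_len = 512L,
                         fusion = c("cca", "sum", "cat", "atten"),
                         variant = c("full", "no_lfem", "no_gfem"),
                         fc_hidden = 256L, dropout = 0.3) {
  fusion <- match.arg(fusion)
  variant <- match.arg(variant)
  cfg <- list(channels = as.integer(channels), timepoints = as.integer(timepoints),
              sampling_rate = as.numeric(sampling_rate),
              n_classes = as.integer(n_classes), k = as.integer(k),
              h = as.integer(h), seq_len = as.integer(seq_len),
              fusion = fusion, variant = variant,
              fc_hidden = as.integer(fc_hidden), dropout = as.numeric(dropout))
  validate_model_config(cfg)
  structure(cfg, class = "model_config")
}

validate_model_config <- function(cfg) {
  stopifnot(cfg$channels >= 2L, cfg$timepoints >= 16L, cfg$n_classes >= 2L,
            cfg$k >= 1L, cfg$h >= 1L, cfg$seq_len >= 1L, cfg$fc_hidden >= 1L,
            cfg$dropout >= 0, cfg$dropout < 1)
  if (cfg$k %% cfg$h != 0L) {
    stop("`k` (", cfg$k, ") must be divisible by the head count `h` (", cfg$h, ")",
         call. = FALSE)
  }
  if (cfg$variant != "no_lfem") {
    sh <- lfem_shapes(cfg$channels, cfg$timepoints, cfg$sampling_rate, cfg$k)
    if (sh$pooled[1] < 1L || sh$pooled[2] < 1L) {
      stop("input geometry too small: pooled feature map would be ",
           sh$pooled[1], " x ", sh$pooled[2], call. = FALSE)
    }
  }
  invisible(cfg)
}

# Shape arithmetic shared by both convolutional pathways: valid convolutions,
# stride 1, then (4, 4) average pooling with stride = window.
lfem_shapes <- function(ch, t, fs, k) {
  kd <- kernel_dims(ch, fs)
  kt <- kd$temporal[2]; kc <- kd$spatial[1]
  if (kt > t) stop("temporal kernel (", kt, ") longer than the trial (", t, ")", call. = FALSE)
  H <- ch - kc + 1L
  W <- t - kt + 1L
  pooled <- c(H %/% 4L, W %/% 4L)
  list(kt = kt, kc = kc,
       conv_t1 = c(k, ch, W), conv_t2 = c(k, H, W),
       conv_s1 = c(k, H, t), conv_s2 = c(k, H, W),
       pooled = pooled, n_positions = pooled[1] * pooled[2])
}

# Canonical parameter layout: one row per tensor, in the exact order the
# C++ core expects. Conv weights are stored as (c_in*kh*kw) x c_out with
# c_in fastest, then kernel row, then kernel column; linear maps as
# (in x out) plus a bias column.
param_layout <- function(cfg) {
  rows <- list()
  add <- function(name, nr, nc, fan, init = "uniform") {
    rows[[length(rows) + 1L]] <<- list(name = name, nrow = nr, ncol = nc,
                                       fan_in = fan, init = init)
  }
  k <- cfg$k
  if (cfg$variant != "no_lfem") {
    sh <- lfem_shapes(cfg$channels, cfg$timepoints, cfg$sampling_rate, k)
    add("conv_t1_w", sh$kt, k, sh$kt)
    add("conv_t2_w", k * sh$kc, k, k * sh$kc)
    add("bn_t_gamma", k, 1L, NA, "one")
    add("bn_t_beta", k, 1L, NA, "zero")
    add("conv_s1_w", sh$kc, k, sh$kc)
    add("conv_s2_w", k * sh$kt, k, k * sh$kt)
    add("bn_s_gamma", k, 1L, NA, "one")
    add("bn_s_beta", k, 1L, NA, "zero")
  } else {
    add("proj_t_w", 1L, k, 1L); add("proj_t_b", k, 1L, 1L)
    add("proj_s_w", 1L, k, 1L); add("proj_s_b", k, 1L, 1L)
  }
  if (cfg$fusion == "cca") {
    for (dir in c("ts", "st")) {
      for (role in c("q", "k", "v")) {
        add(paste0("W", role, "_", dir), k, k, k)
        add(paste0("b", role, "_", dir), k, 1L, k)
      }
    }
    add("alpha", 1L, 1L, NA, "one")
    add("beta", 1L, 1L, NA, "one")
    add("ln_gain", k, 1L, NA, "one")
    add("ln_shift", k, 1L, NA, "zero")
  } else if (cfg$fusion == "cat") {
    add("Wcat", 2L * k, k, 2L * k); add("bcat", k, 1L, 2L * k)
  } else if (cfg$fusion == "atten") {
    add("Wat", 2L * k, 2L, 2L * k); add("bat", 2L, 1L, 2L * k)
  }
  if (cfg$variant != "no_gfem") {
    for (role in c("gq", "gk", "gv", "go")) {
      add(paste0("W", role), k, k, k)
      add(paste0("b", role), k, 1L, k)
    }
  }
  flat_in <- cfg$seq_len * k
  add("W_fc1", flat_in, cfg$fc_hidden, flat_in)
  add("b_fc1", cfg$fc_hidden, 1L, flat_in)
  add("W_fc2", cfg$fc_hidden, cfg$n_classes, cfg$fc_hidden)
  add("b_fc2", cfg$n_classes, 1L, cfg$fc_hidden)

  sizes <- vapply(rows, function(r) r$nrow * r$ncol, numeric(1))
  tibble::tibble(
    name = vapply(rows, `[[`, "", "name"),
    nrow = vapply(rows, function(r) as.integer(r$nrow), integer(1)),
    ncol = vapply(rows, function(r) as.integer(r$ncol), integer(1)),
    fan_in = vapply(rows, function(r) as.numeric(r$fan_in), numeric(1)),
    init = vapply(rows, `[[`, "", "init"),
    offset = cumsum(c(0, sizes[-length(sizes)])),
    size = as.integer(sizes)
  )
}

#' Build a coupled cross-attention network
#'
#' Allocates and initialises all learnable parameters for the configuration:
#' weights and biases draw from `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`
#' (fan-based initialisation), normalisation gains start at 1, shifts at 0,
#' and the two fusion scalars start at 1 (symmetric start).
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for the initialisation draws.
#' @return A `cca_net` object: list with `config`, `layout`, flat parameter
#'   vector `theta`, batch-norm running state `state`, and the build `seed`.
#' @export
build_model <- function(cfg, seed = 1L) {
  validate_model_config(cfg)
  layout <- param_layout(cfg)
  theta <- numeric(sum(layout$size))
  with_local_seed(seed, {
    for (i in seq_len(nrow(layout))) {
      idx <- layout$offset[i] + seq_len(layout$size[i])
      theta[idx] <- switch(layout$init[i],
        uniform = {
          b <- 1 / sqrt(layout$fan_in[i])
          stats::runif(layout$size[i], -b, b)
        },
        one = 1,
        zero = 0)
    }
  })
  state <- if (cfg$variant != "no_lfem") {
    c(rep(0, cfg$k), rep(1, cfg$k), rep(0, cfg$k), rep(1, cfg$k))
  } else numeric(0)
  structure(list(config = cfg, layout = layout, theta = theta, state = state,
                 seed = as.integer(seed)),
            class = "cca_net")
}

#' @export
print.cca_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<cca_net> variant=%s fusion=%s | k=%d h=%d seq_len=%d | %d classes\n",
              cfg$variant, cfg$fusion, cfg$k, cfg$h, cfg$seq_len, cfg$n_classes))
  cat(sprintf("  input: %d channels x %d timepoints @ %g Hz\n",
              cfg$channels, cfg$timepoints, cfg$sampling_rate))
  cat(sprintf("  parameters: %s\n", format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# Named list of parameter matrices (copies) extracted from the flat vector.
net_params <- function(model) {
  lay <- model$layout
  out <- vector("list", nrow(lay))
  names(out) <- lay$name
  for (i in seq_len(nrow(lay))) {
    idx <- lay$offset[i] + seq_len(lay$size[i])
    out[[i]] <- matrix(model$theta[idx], lay$nrow[i], lay$ncol[i])
  }
  out
}

#' Count learnable parameters
#'
#' @param model A `cca_net`.
#' @return Total number of learnable scalars (batch-norm running statistics
#'   are buffers and excluded).
#' @export
count_parameters <- function(model) sum(model$layout$size)

#' Approximate multiply-accumulate count of one forward pass
#'
#' Counts the multiply-accumulate operations of the convolutions, linear
#' projections and attention products for a single trial. Reported for
#' orientation only; published FLOP figures depend on the counting
#' convention and are not comparable across implementations.
#'
#' @param model A `cca_net`.
#' @return Numeric MAC count.
#' @export
count_macs <- function(model) {
  cfg <- model$config
  k <- cfg$k; L <- cfg$seq_len
  macs <- 0
  if (cfg$variant != "no_lfem") {
    sh <- lfem_shapes(cfg$channels, cfg$timepoints, cfg$sampling_rate, k)
    macs <- macs +
      sh$kt * prod(sh$conv_t1) + k * sh$kc * prod(sh$conv_t2) +
      sh$kc * prod(sh$conv_s1) + k * sh$kt * prod(sh$conv_s2)
  } else {
    macs <- macs + 2 * L * k
  }
  attn <- function(width) 2 * L * L * width       # QK' and PV
  if (cfg$fusion == "cca") {
    macs <- macs + 2 * (3 * L * k * k + attn(k))
  } else if (cfg$fusion == "cat") {
    macs <- macs + L * 2 * k * k
  } else if (cfg$fusion == "atten") {
    macs <- macs + 2 * k * 2
  }
  if (cfg$variant != "no_gfem") {
    macs <- macs + 4 * L * k * k + attn(k)        # q,k,v,out projections + heads
  }
  macs + L * k * cfg$fc_hidden + cfg$fc_hidden * cfg$n_classes
}
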