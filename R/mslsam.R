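# Multi-scale stripe local spatial attention (MS-LSAM).
#
# Channel gate: sigmoid(MLP(avg-pool) + MLP(max-pool)) with a shared
# two-layer MLP at reduction r, applied multiplicatively.  Spatial gate:
# the channel-refined map is compressed to a 2-channel mean/max
# descriptor, horizontal 1xk and vertical kx1 strip convolutions are fused
# per kernel length by elementwise max, the three per-length responses are
# averaged and squashed by a sigmoid.  The pre-sigmoid per-length responses
# are retained as a 3-channel strip stack for the reconstruction loss.

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

#' Initialize MS-LSAM parameters
#'
#' @param channels feature channels (the pyramid contract uses 96).
#' @param reduction channel reduction ratio of the shared MLP; must divide
#'   `channels`.
#' @param kernel_lengths strictly increasing odd strip kernel lengths.
#' @param gate_type `"stripe"` (default), `"square"` (the spatial branch is
#'   a single 3x3 convolution, for ablation), or `"uniform"` (constant
#'   gate, control condition).
#' @param bias whether strip convolutions carry biases.
#' @param seed seed for weight initialization.
#' @return Named list of parameter arrays, prefixed for checkpointing.
#' @export
mslsam_init <- function(channels = 96L, reduction = 16L,
                        kernel_lengths = c(7L, 11L, 21L),
                        gate_type = c("stripe", "square", "uniform"),
                        bias = TRUE, seed = 1L) {
  gate_type <- match.arg(gate_type)
  if (channels %% reduction != 0)
    stopf("stripedet_cfg_error", "reduction must divide channels")
  if (gate_type == "stripe") {
    if (any(kernel_lengths %% 2 == 0))
      stopf("stripedet_cfg_error", "kernel lengths must be odd")
    if (any(diff(kernel_lengths) <= 0))
      stopf("stripedet_cfg_error", "kernel lengths must be strictly increasing")
  }
  cr <- channels %/% reduction
  with_seed(seed, {
    p <- list(
      mlp.W1 = he_init(c(channels, cr), channels),
      mlp.b1 = numeric(cr),
      mlp.W2 = he_init(c(cr, channels), cr),
      mlp.b2 = numeric(channels))
    if (gate_type == "stripe") {
      for (k in kernel_lengths) {
        p[[sprintf("strip.h%d.W", k)]] <- he_init(c(1L, 2L, 1L, k), 2 * k)
        p[[sprintf("strip.h%d.b", k)]] <- if (bias) numeric(1) else NULL
        p[[sprintf("strip.v%d.W", k)]] <- he_init(c(1L, 2L, k, 1L), 2 * k)
        p[[sprintf("strip.v%d.b", k)]] <- if (bias) numeric(1) else NULL
      }
      p <- p[!vapply(p, is.null, logical(1))]
    } else if (gate_type == "square") {
      p[["square.W"]] <- he_init(c(1L, 2L, 3L, 3L), 18)
      p[["square.b"]] <- numeric(1)
    }
    attr(p, "config") <- list(channels = channels, reduction = reduction,
                              kernel_lengths = kernel_lengths,
                              gate_type = gate_type, bias = bias)
    p
  })
}

ms_cfg <- function(params) attr(params, "config")

#' Channel attention gate
#'
#' `gate = sigmoid(MLP(avgpool(x)) + MLP(maxpool(x)))`, broadcast over the
#' spatial dimensions.
#' @param x feature node/array, dim `(B, C, H, W)`.
#' @param params from [mslsam_init()].
#' @param tape optional `ad_tape`.
#' @return List with `xprime` (reweighted features) and `gate` (`B x C`
#'   matrix node, values strictly in (0, 1)).
#' @export
channel_gate <- function(x, params, tape = NULL) {
  cfg <- ms_cfg(params)
  if (dim(nv(x))[2] != cfg$channels)
    stopf("stripedet_cfg_error", "input has %d channels, expected %d",
          dim(nv(x))[2], cfg$channels)
  mlp <- function(v) {
    h <- t_relu(t_linear(v, params$mlp.W1, params$mlp.b1, tape), tape)
    t_linear(h, params$mlp.W2, params$mlp.b2, tape)
  }
  gate <- t_sigmoid(t_add(mlp(t_gap(x, tape)), mlp(t_gmp(x, tape)), tape), tape)
  list(xprime = t_mul_channel(x, gate, tape), gate = gate)
}

#' Two-channel spatial descriptor
#'
#' Channel 0 is the mean over channels, channel 1 the max.
#' @inheritParams channel_gate
#' @return Node of dim `(B, 2, H, W)`.
#' @export
spatial_descriptor <- function(x, tape = NULL) {
  t_concat_c(list(t_cmean(x, tape), t_cmax(x, tape)), tape)
}

#' Strip response at one kernel length
#'
#' Elementwise max of the horizontal `1 x k` and vertical `k x 1`
#' convolutions of the 2-channel descriptor, zero-padded to keep the
#' spatial size.
#' @param fs descriptor node, dim `(B, 2, H, W)`.
#' @param k odd kernel length, one of the configured lengths.
#' @inheritParams channel_gate
#' @return Node of dim `(B, 1, H, W)` (pre-sigmoid).
#' @export
strip_response <- function(fs, k, params, tape = NULL) {
  if (k %% 2 == 0) stopf("stripedet_cfg_error", "strip kernel length must be odd")
  cfg <- ms_cfg(params)
  if (!k %in% cfg$kernel_lengths)
    stopf("stripedet_cfg_error", "k = %d is not a configured kernel length", k)
  bh <- params[[sprintf("strip.h%d.b", k)]] %||% 0
  bv <- params[[sprintf("strip.v%d.b", k)]] %||% 0
  ah <- t_conv2d(fs, params[[sprintf("strip.h%d.W", k)]], bh,
                 stride = 1L, padh = 0L, padw = k %/% 2L, tape = tape)
  av <- t_conv2d(fs, params[[sprintf("strip.v%d.W", k)]], bv,
                 stride = 1L, padh = k %/% 2L, padw = 0L, tape = tape)
  t_max2(ah, av, tape)
}

#' Stripe spatial gate and strip stack
#'
#' @param xprime channel-refined features, dim `(B, C, H, W)`.
#' @inheritParams channel_gate
#' @return List with `gate` (`(B, 1, H, W)` node, sigmoid of the mean
#'   per-length response) and `stack` (`(B, 3, H, W)` node of pre-sigmoid
#'   responses, one channel per kernel length).
#' @export
spatial_gate <- function(xprime, params, tape = NULL) {
  cfg <- ms_cfg(params)
  fs <- spatial_descriptor(xprime, tape)
  if (cfg$gate_type == "uniform") {
    d <- dim(nv(xprime))
    z <- array(0, dim = c(d[1], 3L, d[3], d[4]))
    stack <- ad_node(z)
    gate <- ad_node(array(0.5, dim = c(d[1], 1L, d[3], d[4])))
    return(list(gate = gate, stack = stack))
  }
  if (cfg$gate_type == "square") {
    a <- t_conv2d(fs, params$square.W, params$square.b,
                  stride = 1L, padh = 1L, padw = 1L, tape = tape)
    stack <- t_concat_c(list(a, a, a), tape)
    return(list(gate = t_sigmoid(a, tape), stack = stack))
  }
  resp <- lapply(cfg$kernel_lengths, function(k)
    strip_response(fs, k, params, tape))
  stack <- t_concat_c(resp, tape)
  fused <- t_cmean(stack, tape)
  list(gate = t_sigmoid(fused, tape), stack = stack)
}

#' MS-LSAM forward pass
#'
#' Channel gate, then spatial gate, both applied multiplicatively; the
#' output shape equals the input shape and `|refined| <= |x|` elementwise
#' since both gates lie in (0, 1).
#' @inheritParams channel_gate
#' @return List with `refined`, `channel_gate` (`B x C`), `spatial_gate`
#'   (`(B, 1, H, W)`), and `strip_stack` (`(B, 3, H, W)`, pre-sigmoid).
#' @export
mslsam_forward <- function(x, params, tape = NULL) {
  cg <- channel_gate(x, params, tape)
  sg <- spatial_gate(cg$xprime, params, tape)
  refined <- t_mul_spatial(cg$xprime, sg$gate, tape)
  list(refined = refined, channel_gate = cg$gate,
       spatial_gate = sg$gate, strip_stack = sg$stack)
}
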