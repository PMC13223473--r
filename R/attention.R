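# The four attention mechanisms. All blocks are shape-preserving transforms
# of (C, D, H, W) feature maps; gates are multiplicative and bounded.

#' Adaptive kernel size for efficient channel attention
#'
#' Maps a channel count to an odd 1-D convolution kernel size via
#' `k = | log2(C)/gamma + b/gamma |_odd`, so the extent of local
#' cross-channel interaction grows with the channel dimension. When the raw
#' value falls exactly between two odd integers the larger one is chosen,
#' favouring a wider receptive field at high channel counts. The result is
#' floored at 1.
#'
#' @param C channel count (>= 1).
#' @param gamma,b mapping hyperparameters; defaults 2 and 1.
#' @return an odd integer kernel size.
#' @examples
#' dynamic_kernel_size(512)  # 5
#' dynamic_kernel_size(4)    # 1
#' @export
dynamic_kernel_size <- function(C, gamma = 2, b = 1) {
  if (length(C) != 1L || !is.finite(C) || C < 1) {
    stop("dynamic_kernel_size: C must be a single value >= 1")
  }
  if (gamma <= 0) stop("dynamic_kernel_size: gamma must be positive")
  t <- log2(C) / gamma + b / gamma
  lo <- 2 * floor((t - 1) / 2) + 1
  hi <- lo + 2
  k <- if ((t - lo) < (hi - t)) lo else hi
  as.integer(max(1, k))
}

# --- spatial attention -----------------------------------------------------

#' Spatial attention block
#'
#' Aggregates the input over the channel axis with mean and max pooling,
#' concatenates the two single-channel descriptors, convolves them with a
#' `k x k x k` kernel (2 -> 1 channels, same padding) and squashes with a
#' sigmoid to obtain a spatial gate in (0, 1), which multiplies the input
#' voxel-wise. Used independently in the first two encoder stages to keep
#' small, low-level structures (nodule edges and shapes) from being diluted.
#'
#' @param kernel odd convolution kernel size (default 7).
#' @return an `sa_block` whose [forward()] maps `(C,D,H,W)` to `(C,D,H,W)`.
#' @export
spatial_attention_block <- function(kernel = 7L) {
  if (kernel %% 2L != 1L) {
    stop("spatial_attention_block: kernel must be odd, got ", kernel)
  }
  structure(list(conv = conv3d_layer(2L, 1L, k = kernel), kernel = kernel),
            class = "sa_block")
}

#' @export
forward.sa_block <- function(object, x, with_gate = FALSE, ...) {
  st <- channel_pool_stats(x)
  fcat <- ag_concat_channels(list(st$avg, st$max))
  m <- ag_sigmoid(forward(object$conv, fcat))
  out <- ag_mul_spatial(x, m)
  if (with_gate) list(output = out, gate = m) else out
}

#' @export
parameters.sa_block <- function(object, prefix = "") {
  parameters(object$conv, prefix = paste0(prefix, "conv."))
}

# --- dilated multi-scale convolution + efficient channel attention ---------

#' Dilated multi-scale convolution
#'
#' Splits a `(C, D, H, W)` map into four `C/4`-channel groups and convolves
#' each with a depthwise-separable convolution at dilation rates 1, 2, 5, 7
#' (same-padding, spatial shape preserved), then concatenates the groups.
#' Small rates capture fine local detail; large rates widen the receptive
#' field towards global context. The per-group spatial kernel size is
#' [dynamic_kernel_size()] of the full channel count.
#'
#' @param channels input channel count; must be divisible by 4.
#' @param rates integer dilation rates, one per group.
#' @param kernel spatial kernel size override (odd); default adaptive.
#' @return a `dmc_block`.
#' @export
dilated_multiscale_block <- function(channels, rates = c(1L, 2L, 5L, 7L),
                                     kernel = NULL) {
  ng <- length(rates)
  if (channels %% ng != 0L) {
    stop("dilated_multiscale_block: channels (C = ", channels,
         ") must be divisible by the number of dilation groups (", ng, ")")
  }
  k <- kernel %||% dynamic_kernel_size(channels)
  structure(list(
    groups = lapply(rates, function(d) sepconv3d_layer(channels %/% ng, k, d)),
    rates = as.integer(rates), k = k, channels = channels
  ), class = "dmc_block")
}

#' @export
forward.dmc_block <- function(object, x, ...) {
  cg <- object$channels %/% length(object$groups)
  outs <- lapply(seq_along(object$groups), function(i) {
    xi <- ag_slice_channels(x, (i - 1L) * cg + 1L, i * cg)
    forward(object$groups[[i]], xi)
  })
  ag_concat_channels(outs)
}

#' @export
parameters.dmc_block <- function(object, prefix = "") {
  out <- list()
  for (i in seq_along(object$groups)) {
    out <- c(out, parameters(object$groups[[i]],
                             prefix = paste0(prefix, "g", i, ".")))
  }
  out
}

#' Dilated efficient channel attention block
#'
#' Applies [dilated_multiscale_block()] to the input, then derives a channel
#' gate from the concatenated multi-scale map: global average pooling to a
#' length-C descriptor, a same-padded 1-D convolution across channels with
#' adaptive kernel size, a ReLU, and a sigmoid. Because the sigmoid acts on a
#' ReLU output the gate lies in `[0.5, 1)`; it rescales the multi-scale map
#' channel-wise.
#'
#' @inheritParams dilated_multiscale_block
#' @return a `dilated_eca_block`.
#' @export
dilated_eca_block <- function(channels, rates = c(1L, 2L, 5L, 7L),
                              kernel = NULL) {
  k1 <- dynamic_kernel_size(channels)
  structure(list(
    dmc = dilated_multiscale_block(channels, rates, kernel),
    w1d = ag_param(he_init(k1, k1)),
    k1 = k1, channels = channels
  ), class = "eca_block")
}

#' Channel gate of the dilated efficient channel attention block
#'
#' @param object a `dilated_eca_block()`.
#' @param x_concat the concatenated multi-scale feature map.
#' @return length-C gate with entries in `[0.5, 1)`.
#' @export
dilated_eca_gate <- function(object, x_concat) {
  g <- ag_gap(x_concat)
  z <- ag_conv1d_channels(g, object$w1d)
  ag_sigmoid(ag_relu(z))
}

#' @export
forward.eca_block <- function(object, x, with_gate = FALSE, ...) {
  y <- forward(object$dmc, x)
  gate <- dilated_eca_gate(object, y)
  out <- ag_mul_channel(y, gate)
  if (with_gate) list(output = out, gate = gate, concat = y) else out
}

#' @export
parameters.eca_block <- function(object, prefix = "") {
  c(parameters(object$dmc, prefix = paste0(prefix, "dmc.")),
    collect_params(prefix, list(w1d = object$w1d)))
}

# --- convolutional block attention module ----------------------------------

#' Convolutional block attention module (channel then spatial gating)
#'
#' Channel stage: spatial average- and max-pooled length-C descriptors pass
#' through a shared two-layer MLP (hidden width `C / reduction`, ReLU in
#' between); the two branch outputs are combined into a channel gate. Two
#' aggregation modes are supported: `"summed_logits"` (default) adds the
#' branch pre-activations and applies one sigmoid, keeping the gate in (0, 1);
#' `"per_branch_sigmoid"` applies a sigmoid to each branch and adds, giving a
#' gate in (0, 2) that can amplify channels. Spatial stage: the channel-gated
#' map is pooled across channels, the (2, D, H, W) descriptor is convolved
#' with a `kernel^3` filter and squashed to a spatial gate in (0, 1).
#'
#' @param channels input channel count.
#' @param reduction MLP bottleneck reduction ratio (default 16).
#' @param kernel odd spatial kernel size (default 7).
#' @param gate_mode `"summed_logits"` or `"per_branch_sigmoid"`.
#' @return a `cbam_block`.
#' @export
cbam_block <- function(channels, reduction = 16L, kernel = 7L,
                       gate_mode = c("summed_logits", "per_branch_sigmoid")) {
  gate_mode <- match.arg(gate_mode)
  if (kernel %% 2L != 1L) stop("cbam_block: kernel must be odd, got ", kernel)
  if (channels < reduction) {
    stop("cbam_block: channels (", channels,
         ") must be at least the reduction ratio (", reduction, ")")
  }
  hidden <- max(1L, channels %/% reduction)
  structure(list(
    fc1 = dense_layer(channels, hidden),
    fc2 = dense_layer(hidden, channels),
    conv = conv3d_layer(2L, 1L, k = kernel),
    channels = channels, reduction = reduction, kernel = kernel,
    gate_mode = gate_mode
  ), class = "cbam_block")
}

cbam_mlp <- function(object, v) {
  forward(object$fc2, ag_relu(forward(object$fc1, v)))
}

#' Channel gate of a CBAM block
#' @param object a [cbam_block()].
#' @param x input feature map.
#' @return length-C channel gate.
#' @export
cbam_channel_gate <- function(object, x) {
  a <- cbam_mlp(object, ag_gap(x))
  m <- cbam_mlp(object, ag_gmp(x))
  if (object$gate_mode == "summed_logits") {
    ag_sigmoid(ag_add(a, m))
  } else {
    ag_add(ag_sigmoid(a), ag_sigmoid(m))
  }
}

#' Spatial gate of a CBAM block applied to the channel-gated map
#' @param object a [cbam_block()].
#' @param f_c channel-gated feature map.
#' @param with_gate also return the gate map.
#' @return gated feature map (and the `(1,D,H,W)` gate when requested).
#' @export
cbam_spatial_gate <- function(object, f_c, with_gate = FALSE) {
  st <- channel_pool_stats(f_c)
  fcat <- ag_concat_channels(list(st$avg, st$max))
  m <- ag_sigmoid(forward(object$conv, fcat))
  out <- ag_mul_spatial(f_c, m)
  if (with_gate) list(output = out, gate = m) else out
}

#' @export
forward.cbam_block <- function(object, x, with_gate = FALSE, ...) {
  cg <- cbam_channel_gate(object, x)
  fc <- ag_mul_channel(x, cg)
  sp <- cbam_spatial_gate(object, fc, with_gate = with_gate)
  if (with_gate) {
    list(output = sp$output, channel_gate = cg, spatial_gate = sp$gate)
  } else {
    sp
  }
}

#' @export
parameters.cbam_block <- function(object, prefix = "") {
  c(parameters(object$fc1, prefix = paste0(prefix, "fc1.")),
    parameters(object$fc2, prefix = paste0(prefix, "fc2.")),
    parameters(object$conv, prefix = paste0(prefix, "conv.")))
}

# --- squeeze and excitation ------------------------------------------------

#' Squeeze-and-excitation block
#'
#' Global average pooling compresses the input to a length-C descriptor,
#' which two fully connected layers (`C -> C/r`, ReLU, `C/r -> C`, sigmoid)
#' turn into per-channel weights in (0, 1) that recalibrate the input. Used
#' on the gated skip connections so the decoder receives the most relevant
#' encoder channels.
#'
#' @param channels input channel count.
#' @param reduction bottleneck reduction ratio (default 16); the hidden
#'   width is `max(1, channels %/% reduction)`.
#' @return an `se_block`.
#' @export
se_block <- function(channels, reduction = 16L) {
  hidden <- max(1L, channels %/% reduction)
  structure(list(
    fc1 = dense_layer(channels, hidden),
    fc2 = dense_layer(hidden, channels),
    channels = channels, reduction = reduction
  ), class = "se_block")
}

#' @export
forward.se_block <- function(object, x, with_gate = FALSE, ...) {
  s <- ag_sigmoid(forward(object$fc2, ag_relu(forward(object$fc1, ag_gap(x)))))
  out <- ag_mul_channel(x, s)
  if (with_gate) list(output = out, gate = s) else out
}

#' @export
parameters.se_block <- function(object, prefix = "") {
  c(parameters(object$fc1, prefix = paste0(prefix, "fc1.")),
    parameters(object$fc2, prefix = paste0(prefix, "fc2.")))
}
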