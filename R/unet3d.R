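# Three-level residual 3D U-Net with stage-specific attention placement:
# spatial attention in the first two encoder stages, dilated efficient
# channel attention in the third, CBAM in the first and last decoder stages,
# and squeeze-and-excitation gating on the first skip connection and on the
# bottleneck feature entering the decoder.

#' Network configuration
#'
#' @param variant one of `"baseline"` (plain residual U-Net),
#'   `"sa"`, `"sa_eca"`, `"sa_eca_cbam"`, `"enhanced"` (all attention plus
#'   squeeze-and-excitation). The intermediate variants form the ablation
#'   lattice: each step enables exactly one extra mechanism.
#' @param base_channels channels of the first encoder stage (doubled at each
#'   of the three down-stages); 64 reproduces the reference layout.
#' @param dropout_rate channel-dropout rate applied at the end of every
#'   down/up stage.
#' @param sa_kernel spatial-attention kernel size (odd).
#' @param cbam_reduction,se_reduction attention bottleneck ratios; at each
#'   site the effective ratio is capped at that site's channel count.
#' @param cbam_gate_mode see [cbam_block()].
#' @param eca_rates dilation rates of the multi-scale bottleneck attention.
#' @return a `unet3d_config` list.
#' @export
unet3d_config <- function(variant = c("enhanced", "baseline", "sa", "sa_eca",
                                      "sa_eca_cbam"),
                          base_channels = 64L, dropout_rate = 0.1,
                          sa_kernel = 7L, cbam_reduction = 16L,
                          se_reduction = 16L,
                          cbam_gate_mode = "summed_logits",
                          eca_rates = c(1L, 2L, 5L, 7L)) {
  variant <- match.arg(variant)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("unet3d_config: dropout_rate must lie in [0, 1)")
  }
  toggles <- switch(variant,
    baseline     = c(sa = FALSE, eca = FALSE, cbam = FALSE, se = FALSE),
    sa           = c(sa = TRUE,  eca = FALSE, cbam = FALSE, se = FALSE),
    sa_eca       = c(sa = TRUE,  eca = TRUE,  cbam = FALSE, se = FALSE),
    sa_eca_cbam  = c(sa = TRUE,  eca = TRUE,  cbam = TRUE,  se = FALSE),
    enhanced     = c(sa = TRUE,  eca = TRUE,  cbam = TRUE,  se = TRUE)
  )
  structure(list(variant = variant, base_channels = as.integer(base_channels),
                 dropout_rate = dropout_rate, sa_kernel = as.integer(sa_kernel),
                 cbam_reduction = as.integer(cbam_reduction),
                 se_reduction = as.integer(se_reduction),
                 cbam_gate_mode = cbam_gate_mode,
                 eca_rates = as.integer(eca_rates),
                 use = toggles),
            class = "unet3d_config")
}

#' Ablation lattice of network variants
#'
#' @return character vector of variant names ordered by incrementally added
#'   mechanisms.
#' @export
ablation_variants <- function() {
  c("baseline", "sa", "sa_eca", "sa_eca_cbam", "enhanced")
}

# residual double convolution: (conv3 -> BN -> ReLU) x2 + shortcut
double_conv_block <- function(in_ch, out_ch) {
  structure(list(
    conv1 = conv3d_layer(in_ch, out_ch, k = 3L),
    bn1 = batchnorm3d(out_ch),
    conv2 = conv3d_layer(out_ch, out_ch, k = 3L),
    bn2 = batchnorm3d(out_ch),
    proj = if (in_ch != out_ch) conv3d_layer(in_ch, out_ch, k = 1L) else NULL,
    in_ch = in_ch, out_ch = out_ch
  ), class = "double_conv")
}

#' @export
forward.double_conv <- function(object, x, training = FALSE, ...) {
  h <- ag_relu(forward(object$bn1, forward(object$conv1, x),
                       training = training))
  h <- ag_relu(forward(object$bn2, forward(object$conv2, h),
                       training = training))
  sc <- if (is.null(object$proj)) x else forward(object$proj, x)
  ag_add(h, sc)
}

#' @export
parameters.double_conv <- function(object, prefix = "") {
  collect_params(prefix, list(conv1 = object$conv1, bn1 = object$bn1,
                              conv2 = object$conv2, bn2 = object$bn2,
                              proj = object$proj))
}

down_stage_block <- function(in_ch, out_ch, attn = NULL, dropout = 0.1) {
  structure(list(dc = double_conv_block(in_ch, out_ch), attn = attn,
                 dropout = dropout),
            class = "down_stage")
}

#' @export
forward.down_stage <- function(object, x, training = FALSE,
                               bypass_attention = FALSE, ...) {
  h <- forward(object$dc, ag_maxpool2(x), training = training)
  if (!is.null(object$attn) && !bypass_attention) {
    h <- forward(object$attn, h, training = training)
  }
  ag_dropout_channel(h, object$dropout, training)
}

#' @export
parameters.down_stage <- function(object, prefix = "") {
  collect_params(prefix, list(dc = object$dc, attn = object$attn))
}

up_stage_block <- function(in_ch, skip_ch, out_ch, attn = NULL,
                           dropout = 0.1) {
  structure(list(dc = double_conv_block(in_ch + skip_ch, out_ch),
                 attn = attn, dropout = dropout,
                 in_ch = in_ch, skip_ch = skip_ch, out_ch = out_ch),
            class = "up_stage")
}

#' @export
forward.up_stage <- function(object, x, skip, training = FALSE,
                             bypass_attention = FALSE, ...) {
  up <- ag_upsample2(x)
  du <- dim(ag_value(up)); ds <- dim(ag_value(skip))
  if (!all(du[-1] == ds[-1])) {
    stop("up_stage: upsampled shape (", paste(du, collapse = "x"),
         ") does not spatially match skip shape (",
         paste(ds, collapse = "x"), ")")
  }
  h <- forward(object$dc, ag_concat_channels(list(up, skip)),
               training = training)
  if (!is.null(object$attn) && !bypass_attention) {
    h <- forward(object$attn, h, training = training)
  }
  ag_dropout_channel(h, object$dropout, training)
}

#' @export
parameters.up_stage <- function(object, prefix = "") {
  collect_params(prefix, list(dc = object$dc, attn = object$attn))
}

#' Build the segmentation network
#'
#' Assembles the three-level encoder/decoder with the attention placement of
#' the given configuration. The encoder stages use channels
#' `F, 2F, 4F, 8F` for `F = base_channels`; the decoder mirrors them.
#'
#' @param cfg a [unet3d_config()].
#' @return a `unet3d` model object.
#' @export
build_unet3d <- function(cfg = unet3d_config()) {
  stopifnot(inherits(cfg, "unet3d_config"))
  FF <- cfg$base_channels
  use <- cfg$use
  dr <- cfg$dropout_rate
  red <- function(ratio, ch) min(ratio, ch)
  mk_cbam <- function(ch) {
    cbam_block(ch, reduction = red(cfg$cbam_reduction, ch),
               kernel = 7L, gate_mode = cfg$cbam_gate_mode)
  }
  model <- structure(list(
    cfg = cfg,
    inc = double_conv_block(1L, FF),
    down1 = down_stage_block(FF, 2L * FF,
      attn = if (use[["sa"]]) spatial_attention_block(cfg$sa_kernel),
      dropout = dr),
    down2 = down_stage_block(2L * FF, 4L * FF,
      attn = if (use[["sa"]]) spatial_attention_block(cfg$sa_kernel),
      dropout = dr),
    down3 = down_stage_block(4L * FF, 8L * FF,
      attn = if (use[["eca"]]) dilated_eca_block(8L * FF, cfg$eca_rates),
      dropout = dr),
    se1 = if (use[["se"]]) se_block(2L * FF, red(cfg$se_reduction, 2L * FF)),
    se2 = if (use[["se"]]) se_block(8L * FF, red(cfg$se_reduction, 8L * FF)),
    up1 = up_stage_block(8L * FF, 4L * FF, 4L * FF,
      attn = if (use[["cbam"]]) mk_cbam(4L * FF), dropout = dr),
    up2 = up_stage_block(4L * FF, 2L * FF, 2L * FF, attn = NULL,
                         dropout = dr),
    up3 = up_stage_block(2L * FF, 1L * FF, 1L * FF,
      attn = if (use[["cbam"]]) mk_cbam(FF), dropout = dr),
    outc = conv3d_layer(FF, 1L, k = 1L)
  ), class = "unet3d")
  model
}

#' @export
parameters.unet3d <- function(object, prefix = "") {
  collect_params(prefix, list(
    inc = object$inc, down1 = object$down1, down2 = object$down2,
    down3 = object$down3, se1 = object$se1, se2 = object$se2,
    up1 = object$up1, up2 = object$up2, up3 = object$up3,
    outc = object$outc))
}

#' Number of trainable parameters of a model
#' @param model a layer or model object.
#' @return integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(parameters(model), function(p) length(p$value), numeric(1)))
}

#' Forward pass of the segmentation network
#'
#' @param object a `unet3d` model.
#' @param x input patch of shape `(1, D, H, W)`; spatial dims must be
#'   divisible by 8 (three pooling levels).
#' @param training enable BatchNorm batch statistics and dropout.
#' @param bypass_attention skip all attention and SE modules (used for
#'   baseline-equivalence checks).
#' @param with_ledger also return the per-stage shape ledger.
#' @param ... unused.
#' @return logits of shape `(1, D, H, W)` (an `ag_tensor` while gradients are
#'   enabled), or `list(logits, ledger)` when `with_ledger = TRUE`.
#' @export
forward.unet3d <- function(object, x, training = FALSE,
                           bypass_attention = FALSE, with_ledger = FALSE,
                           ...) {
  d <- dim(ag_value(x))
  if (is.null(d) || length(d) != 4L || d[1] != 1L) {
    stop("unet3d: input must be a (1, D, H, W) array")
  }
  if (any(d[-1] %% 8L != 0L)) {
    stop("unet3d: spatial dims (", paste(d[-1], collapse = ", "),
         ") must be divisible by 8")
  }
  led <- list()
  note <- function(stage, v) {
    if (with_ledger) led[[length(led) + 1L]] <<-
        data.frame(stage = stage,
                   shape = paste(dim(ag_value(v)), collapse = "x"))
    v
  }
  x1 <- note("DoubleConv3D", forward(object$inc, x, training = training))
  d1 <- note("Down3D-1", forward(object$down1, x1, training = training,
                                 bypass_attention = bypass_attention))
  d2 <- note("Down3D-2", forward(object$down2, d1, training = training,
                                 bypass_attention = bypass_attention))
  d3 <- note("Down3D-3", forward(object$down3, d2, training = training,
                                 bypass_attention = bypass_attention))
  s1 <- if (!is.null(object$se1) && !bypass_attention) {
    forward(object$se1, d1, training = training)
  } else d1
  s2 <- if (!is.null(object$se2) && !bypass_attention) {
    forward(object$se2, d3, training = training)
  } else d3
  note("SEBlock-1", s1); note("SEBlock-2", s2)
  u1 <- note("Up3D-1", forward(object$up1, s2, skip = d2,
                               training = training,
                               bypass_attention = bypass_attention))
  u2 <- note("Up3D-2", forward(object$up2, u1, skip = s1,
                               training = training,
                               bypass_attention = bypass_attention))
  u3 <- note("Up3D-3", forward(object$up3, u2, skip = x1,
                               training = training,
                               bypass_attention = bypass_attention))
  logits <- note("OutputConv3D", forward(object$outc, u3))
  if (with_ledger) {
    list(logits = logits, ledger = do.call(rbind, led))
  } else {
    logits
  }
}

#' Expected per-stage output shapes for a given configuration
#'
#' @param base_channels first-stage channel count.
#' @param input_dim spatial input dims `(D, H, W)`.
#' @return data.frame with columns `stage`, `shape`, ordered as the forward
#'   ledger.
#' @export
unet3d_expected_shapes <- function(base_channels = 64L,
                                   input_dim = c(16L, 96L, 96L)) {
  FF <- base_channels
  s <- function(ch, div) paste(c(ch, input_dim %/% div), collapse = "x")
  data.frame(
    stage = c("DoubleConv3D", "Down3D-1", "Down3D-2", "Down3D-3",
              "SEBlock-1", "SEBlock-2", "Up3D-1", "Up3D-2", "Up3D-3",
              "OutputConv3D"),
    shape = c(s(FF, 1L), s(2L * FF, 2L), s(4L * FF, 4L), s(8L * FF, 8L),
              s(2L * FF, 2L), s(8L * FF, 8L), s(4L * FF, 4L), s(2L * FF, 2L),
              s(FF, 1L), s(1L, 1L))
  )
}

# --- checkpointing ---------------------------------------------------------

#' Save a model checkpoint
#'
#' Single-file archive holding the configuration, all parameter values,
#' BatchNorm running statistics, and free-form metadata (epoch, best
#' validation Dice, seed, ...).
#'
#' @param model a `unet3d` model.
#' @param path output file.
#' @param meta named list of metadata.
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  saveRDS(list(cfg = model$cfg, state = module_state(model), meta = meta),
          path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()].
#' @return list with elements `model` and `meta`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_unet3d(ck$cfg)
  load_module_state(model, ck$state)
  list(model = model, meta = ck$meta)
}
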