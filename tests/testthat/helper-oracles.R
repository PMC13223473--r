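# Naive nested-loop reference implementations, independent of the package's
# vectorized im2col/GEMM paths. Used only on tiny inputs.

# bind the internal engine symbols the oracles need; when the package is not
# installed (plain sourcing during development) the globals are used instead
.engine_internals <- c(
  "ag_value", "ag_param", "ag_backward", "zero_grads", "with_no_grad",
  "is_ag", "conv3d_forward", "conv3d_backward", "ag_conv3d", "ag_depthwise",
  "ag_pointwise", "ag_maxpool2", "ag_upsample2", "ag_batchnorm",
  "ag_seg_loss", "ag_relu", "ag_sigmoid", "ag_add", "ag_mul", "ag_gap",
  "ag_gmp",
  "ag_dense", "ag_conv1d_channels", "ag_mul_channel", "ag_mul_spatial",
  "ag_concat_channels", "ag_slice_channels", "ag_mean_all",
  "seg_loss_with_grad", "module_state", "load_module_state", "batchnorm3d",
  "conv3d_layer", "dense_layer", "sepconv3d_layer", "he_init",
  "optimizer_state", "optimizer_step", "micro_f1", "nodule_mask",
  "pso_evaluate", "clamp_prob", "interp_axis3", "polygon_fill",
  "rotate_inplane", "flip_axis3")
if (requireNamespace("nodseg3d", quietly = TRUE)) {
  for (.nm in .engine_internals) {
    assign(.nm, utils::getFromNamespace(.nm, "nodseg3d"))
  }
}

# x: (Cin, D, H, W); Wm: (Cin * k^3) x Cout packed channel-fastest with taps
# ordered (kd, kh, kw), kd fastest — the packing documented in conv-ops.R
naive_conv3d <- function(x, Wm, bias, k, dil = 1L) {
  d <- dim(x); Cin <- d[1]; D <- d[2]; H <- d[3]; W <- d[4]
  Cout <- ncol(Wm)
  Wa <- array(Wm, c(Cin, k, k, k, Cout))
  p <- dil * (k - 1) / 2
  out <- array(0, c(Cout, D, H, W))
  for (co in 1:Cout) for (dd in 1:D) for (hh in 1:H) for (ww in 1:W) {
    acc <- if (is.null(bias)) 0 else bias[co]
    for (i in 1:k) for (j in 1:k) for (l in 1:k) {
      zd <- dd + (i - 1) * dil - p
      zh <- hh + (j - 1) * dil - p
      zw <- ww + (l - 1) * dil - p
      if (zd >= 1 && zd <= D && zh >= 1 && zh <= H && zw >= 1 && zw <= W) {
        for (c in 1:Cin) {
          acc <- acc + Wa[c, i, j, l, co] * x[c, zd, zh, zw]
        }
      }
    }
    out[co, dd, hh, ww] <- acc
  }
  out
}

# depthwise (per-channel) dilated convolution; W: C x k^3 (taps kd fastest)
naive_depthwise <- function(x, W, b, k, dil = 1L) {
  d <- dim(x); C <- d[1]
  out <- array(0, d)
  for (c in 1:C) {
    Wm <- matrix(W[c, ], ncol = 1)
    xc <- x[c, , , , drop = FALSE]
    out[c, , , ] <- naive_conv3d(xc, Wm, if (is.null(b)) NULL else b[c],
                                 k, dil)
  }
  out
}

sigmoid_ref <- function(z) 1 / (1 + exp(-z))

# spatial attention: channel mean/max pool -> k^3 conv (2 -> 1) -> sigmoid
naive_sa <- function(block, x) {
  d <- dim(x)
  avg <- apply(x, 2:4, mean)
  mx <- apply(x, 2:4, max)
  f <- array(0, c(2, d[2], d[3], d[4]))
  f[1, , , ] <- avg; f[2, , , ] <- mx
  Wm <- ag_value(block$conv$W)
  b <- as.vector(ag_value(block$conv$b))
  gate <- sigmoid_ref(naive_conv3d(f, Wm, b, block$kernel))
  out <- x
  for (c in seq_len(d[1])) out[c, , , ] <- x[c, , , ] * gate[1, , , ]
  out
}

# dilated multi-scale conv: channel groups through depthwise-separable convs
naive_dmc <- function(block, x) {
  d <- dim(x)
  ng <- length(block$groups)
  cg <- d[1] %/% ng
  out <- array(0, d)
  for (i in seq_len(ng)) {
    g <- block$groups[[i]]
    xi <- x[((i - 1) * cg + 1):(i * cg), , , , drop = FALSE]
    dw <- naive_depthwise(xi, ag_value(g$dw_W), as.vector(ag_value(g$dw_b)),
                          g$k, g$dilation)
    pw <- ag_value(g$pw_W)   # cg x cg pointwise
    pb <- as.vector(ag_value(g$pw_b))
    for (dd in 1:d[2]) for (hh in 1:d[3]) for (ww in 1:d[4]) {
      out[((i - 1) * cg + 1):(i * cg), dd, hh, ww] <-
        t(pw) %*% dw[, dd, hh, ww] + pb
    }
  }
  out
}

naive_conv1d_channels <- function(v, w) {
  k <- length(w); p <- (k - 1) / 2; C <- length(v)
  out <- numeric(C)
  for (c in 1:C) {
    for (i in 1:k) {
      z <- c + i - 1 - p
      if (z >= 1 && z <= C) out[c] <- out[c] + w[i] * v[z]
    }
  }
  out
}

naive_eca <- function(block, x) {
  y <- naive_dmc(block$dmc, x)
  gap <- apply(y, 1, mean)
  z <- naive_conv1d_channels(gap, as.vector(ag_value(block$w1d)))
  gate <- sigmoid_ref(pmax(z, 0))
  out <- y
  for (c in seq_len(dim(x)[1])) out[c, , , ] <- y[c, , , ] * gate[c]
  out
}

naive_dense <- function(layer, v) {
  as.vector(t(ag_value(layer$W)) %*% v + as.vector(ag_value(layer$b)))
}

naive_cbam <- function(block, x) {
  d <- dim(x)
  mlp <- function(v) {
    naive_dense(block$fc2, pmax(naive_dense(block$fc1, v), 0))
  }
  a <- mlp(apply(x, 1, mean))
  m <- mlp(apply(x, 1, max))
  cg <- if (block$gate_mode == "summed_logits") sigmoid_ref(a + m)
        else sigmoid_ref(a) + sigmoid_ref(m)
  fc <- x
  for (c in seq_len(d[1])) fc[c, , , ] <- x[c, , , ] * cg[c]
  avg <- apply(fc, 2:4, mean)
  mx <- apply(fc, 2:4, max)
  f <- array(0, c(2, d[2], d[3], d[4]))
  f[1, , , ] <- avg; f[2, , , ] <- mx
  sg <- sigmoid_ref(naive_conv3d(f, ag_value(block$conv$W),
                                 as.vector(ag_value(block$conv$b)),
                                 block$kernel))
  out <- fc
  for (c in seq_len(d[1])) out[c, , , ] <- fc[c, , , ] * sg[1, , , ]
  out
}

naive_se <- function(block, x) {
  gap <- apply(x, 1, mean)
  s <- sigmoid_ref(naive_dense(block$fc2,
                               pmax(naive_dense(block$fc1, gap), 0)))
  out <- x
  for (c in seq_len(dim(x)[1])) out[c, , , ] <- x[c, , , ] * s[c]
  out
}

# finite-difference gradient of f at x for a few sampled entries
fd_grad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

rand_arr <- function(...) array(stats::rnorm(prod(c(...))), c(...))
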