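# im2col-based 3D convolution and the remaining structural ops.
#
# Feature maps are numeric arrays with dim (C, D, H, W); channel fastest, so
# matrix(x, nrow = C) is the C x (D*H*W) view with voxels in (d, h, w)
# column-major order. Convolution weights are stored pre-flattened as a
# (Cin * k^3) x Cout matrix whose row order is channel-fastest, then kernel
# taps in (i, j, l) order, matching the im2col gather below, so the forward
# pass is a single BLAS GEMM per voxel slab.

.IM2COL_LIMIT <- 2.5e7  # max elements of a gathered column block

# padded tap coordinate tables for one spatial shape
conv3d_tap_tables <- function(D, H, W, k, dil) {
  p <- as.integer(dil * (k - 1L) / 2L)
  Dp <- D + 2L * p; Hp <- H + 2L * p; Wp <- W + 2L * p
  steps <- seq(0L, by = dil, length.out = k)
  list(
    p = p, Dp = Dp, Hp = Hp, Wp = Wp,
    dd = outer(steps, seq_len(D), "+"),
    hh = (outer(steps, seq_len(H), "+") - 1L) * Dp,
    ww = (outer(steps, seq_len(W), "+") - 1L) * (Dp * Hp)
  )
}

# gather-index matrix (k^3 x D*H*Wn) for a slab of output W-columns
conv3d_slab_index <- function(tt, ws, k) {
  tmp <- outer(tt$dd, tt$hh, "+")                    # (k, D, k, H)
  tmp <- outer(tmp, tt$ww[, ws, drop = FALSE], "+")  # (k, D, k, H, k, Wn)
  S <- aperm(tmp, c(1, 3, 5, 2, 4, 6))
  S <- as.integer(S)
  dim(S) <- c(k^3, length(S) / k^3)
  S
}

# cached slab index list for one (shape, kernel, dilation); small shapes are
# memoized because every training iteration reuses them
conv3d_slab_set <- function(tt, Cin, k, dil, D, H, W) {
  key <- paste(D, H, W, k, dil, Cin, sep = "_")
  hit <- .ns$im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  slabs <- conv3d_slabs(Cin, k, D, H, W)
  out <- lapply(slabs, function(ws) {
    list(ws = ws, S = conv3d_slab_index(tt, ws, k))
  })
  if (k^3 * D * H * W <= 4e6) .ns$im2col_cache[[key]] <- out
  out
}

pad_spatial <- function(x, p) {
  d <- dim(x)
  if (p == 0L) return(x)
  xp <- array(0, c(d[1], d[2] + 2L * p, d[3] + 2L * p, d[4] + 2L * p))
  xp[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), (p + 1):(p + d[4])] <- x
  xp
}

conv3d_slabs <- function(Cin, k, D, H, W) {
  per_w <- max(Cin, 4L) * k^3 * D * H
  nw <- max(1L, as.integer(.IM2COL_LIMIT / per_w))
  split(seq_len(W), ceiling(seq_len(W) / nw))
}

# full (uncut) gather index as a per-tap list of contiguous index vectors,
# cached when small
conv3d_full_index <- function(tt, k, dil, D, H, W) {
  key <- paste("full", D, H, W, k, dil, sep = "_")
  tl <- .ns$im2col_cache[[key]]
  if (is.null(tl)) {
    S <- conv3d_slab_index(tt, seq_len(W), k)
    tl <- lapply(seq_len(nrow(S)), function(t) S[t, ])
    if (length(S) <= 4e6) .ns$im2col_cache[[key]] <- tl
  }
  tl
}

# padded per-channel planes as plain vectors (fast scalar-index gathers)
pad_channel_vectors <- function(x, p, d) {
  D <- d[2]; H <- d[3]; W <- d[4]
  Dp <- D + 2L * p; Hp <- H + 2L * p; Wp <- W + 2L * p
  lapply(seq_len(d[1]), function(c) {
    xc <- array(0, c(Dp, Hp, Wp))
    xc[(p + 1):(p + D), (p + 1):(p + H), (p + 1):(p + W)] <- x[c, , , ]
    as.vector(xc)
  })
}

# low-channel direct path: loop kernel taps, gathering from cache-resident
# padded planes; beats the im2col GEMM when Cin*Cout is tiny (the 2 -> 1
# spatial-attention gate convolutions with k = 7)
conv3d_forward_small <- function(x, Wm, bias, k, dil, tt, d) {
  Cin <- d[1]; N <- prod(d[-1])
  Cout <- ncol(Wm)
  k3 <- k^3
  S <- conv3d_full_index(tt, k, dil, d[2], d[3], d[4])
  xc <- pad_channel_vectors(x, tt$p, d)
  Wa <- Wm; dim(Wa) <- c(Cin, k3, Cout)
  out <- vector("list", Cout)
  for (co in seq_len(Cout)) out[[co]] <- numeric(N)
  for (t in seq_len(k3)) {
    idx <- S[[t]]
    for (c in seq_len(Cin)) {
      g <- xc[[c]][idx]
      for (co in seq_len(Cout)) {
        w <- Wa[c, t, co]
        if (w != 0) out[[co]] <- out[[co]] + w * g
      }
    }
  }
  res <- do.call(rbind, out)
  if (!is.null(bias)) res <- res + as.vector(bias)
  dim(res) <- c(Cout, d[-1])
  res
}

conv3d_gradw_small <- function(x, gm, k, dil, tt, d, Cout) {
  Cin <- d[1]; k3 <- k^3
  S <- conv3d_full_index(tt, k, dil, d[2], d[3], d[4])
  xc <- pad_channel_vectors(x, tt$p, d)
  gW <- matrix(0, Cin * k3, Cout)
  grows <- lapply(seq_len(Cout), function(co) gm[co, ])
  for (t in seq_len(k3)) {
    idx <- S[[t]]
    for (c in seq_len(Cin)) {
      g <- xc[[c]][idx]
      for (co in seq_len(Cout)) {
        gW[(t - 1L) * Cin + c, co] <- sum(g * grows[[co]])
      }
    }
  }
  gW
}

conv3d_forward <- function(x, Wm, bias, k, dil = 1L) {
  d <- dim(x); Cin <- d[1]; D <- d[2]; H <- d[3]; W <- d[4]
  Cout <- ncol(Wm)
  tt <- conv3d_tap_tables(D, H, W, k, dil)
  if (Cin * Cout <= 8L && k^3 * D * H * W <= 4e6) {
    return(conv3d_forward_small(x, Wm, bias, k, dil, tt, d))
  }
  xpm <- matrix(pad_spatial(x, tt$p), nrow = Cin)
  out <- matrix(0, Cout, D * H * W)
  DH <- D * H
  for (sl in conv3d_slab_set(tt, Cin, k, dil, D, H, W)) {
    cols <- xpm[, sl$S, drop = FALSE]
    dim(cols) <- c(Cin * k^3, ncol(sl$S))
    ws <- sl$ws
    vcols <- ((ws[1] - 1L) * DH + 1L):(ws[length(ws)] * DH)
    out[, vcols] <- crossprod(Wm, cols)
  }
  if (!is.null(bias)) out <- out + as.vector(bias)
  dim(out) <- c(Cout, D, H, W)
  out
}

# channel-transposed, tap-flipped weight matrix: for a stride-1, odd-kernel,
# same-padded convolution the input gradient is itself such a convolution of
# the output gradient with these weights
conv3d_flip_weights <- function(Wm, Cin, k) {
  k3 <- k^3
  Cout <- ncol(Wm)
  arr <- Wm
  dim(arr) <- c(Cin, k3, Cout)
  arr <- aperm(arr[, k3:1, , drop = FALSE], c(3, 2, 1))
  dim(arr) <- c(Cout * k3, Cin)
  arr
}

conv3d_backward <- function(x, Wm, k, dil, gout) {
  d <- dim(x); Cin <- d[1]; D <- d[2]; H <- d[3]; W <- d[4]
  Cout <- ncol(Wm)
  tt <- conv3d_tap_tables(D, H, W, k, dil)
  gm <- matrix(gout, nrow = Cout)
  DH <- D * H
  k3 <- k^3
  if (Cin * Cout <= 8L && k3 * D * H * W <= 4e6) {
    gW <- conv3d_gradw_small(x, gm, k, dil, tt, d, Cout)
  } else {
    xpm <- matrix(pad_spatial(x, tt$p), nrow = Cin)
    gW <- matrix(0, nrow(Wm), Cout)
    for (sl in conv3d_slab_set(tt, Cin, k, dil, D, H, W)) {
      cols <- xpm[, sl$S, drop = FALSE]
      dim(cols) <- c(Cin * k3, ncol(sl$S))
      ws <- sl$ws
      vcols <- ((ws[1] - 1L) * DH + 1L):(ws[length(ws)] * DH)
      gW <- gW + cols %*% t(gm[, vcols, drop = FALSE])
    }
  }
  gx <- conv3d_forward(gout, conv3d_flip_weights(Wm, Cin, k), NULL, k, dil)
  list(gx, gW, rowSums(gm))
}

ag_conv3d <- function(x, W, b, k, dil = 1L) {
  xv <- ag_value(x); Wv <- ag_value(W)
  bv <- if (is.null(b)) NULL else ag_value(b)
  out <- conv3d_forward(xv, Wv, bv, k, dil)
  inputs <- if (is.null(b)) list(x, W) else list(x, W, b)
  ag_op(out, inputs, function(g) {
    gr <- conv3d_backward(xv, Wv, k, dil, g)
    if (is.null(b)) gr[1:2] else gr
  })
}

# pointwise (1x1x1) convolution: W is Cin x Cout
ag_pointwise <- function(x, W, b = NULL) {
  xv <- ag_value(x); Wv <- ag_value(W)
  d <- dim(xv); Cin <- d[1]
  xm <- matrix(xv, nrow = Cin)
  out <- crossprod(Wv, xm)
  if (!is.null(b)) out <- out + as.vector(ag_value(b))
  dim(out) <- c(ncol(Wv), d[-1])
  inputs <- if (is.null(b)) list(x, W) else list(x, W, b)
  ag_op(out, inputs, function(g) {
    gm <- matrix(g, nrow = ncol(Wv))
    gx <- Wv %*% gm
    dim(gx) <- d
    gW <- xm %*% t(gm)
    if (is.null(b)) list(gx, gW) else list(gx, gW, rowSums(gm))
  })
}

# depthwise (per-channel) dilated convolution: W is C x k^3, bias length C
ag_depthwise <- function(x, W, b, k, dil = 1L) {
  xv <- ag_value(x); Wv <- ag_value(W)
  bv <- if (is.null(b)) NULL else as.vector(ag_value(b))
  d <- dim(xv); C <- d[1]; D <- d[2]; H <- d[3]; W4 <- d[4]
  tt <- conv3d_tap_tables(D, H, W4, k, dil)
  xpm <- matrix(pad_spatial(xv, tt$p), nrow = C)
  dkey <- paste("dw", D, H, W4, k, dil, sep = "_")
  S <- .ns$im2col_cache[[dkey]]
  if (is.null(S)) {
    S <- conv3d_slab_index(tt, seq_len(W4), k)
    if (length(S) <= 4e6) .ns$im2col_cache[[dkey]] <- S
  }
  k3 <- k^3
  out <- matrix(0, C, D * H * W4)
  for (t in seq_len(k3)) out <- out + xpm[, S[t, ], drop = FALSE] * Wv[, t]
  if (!is.null(bv)) out <- out + bv
  dim(out) <- c(C, D, H, W4)
  inputs <- if (is.null(b)) list(x, W) else list(x, W, b)
  ag_op(out, inputs, function(g) {
    gm <- matrix(g, nrow = C)
    gW <- matrix(0, C, k3)
    gxpm <- matrix(0, C, tt$Dp * tt$Hp * tt$Wp)
    for (t in seq_len(k3)) {
      idx <- S[t, ]
      gW[, t] <- rowSums(gm * xpm[, idx, drop = FALSE])
      gxpm[, idx] <- gxpm[, idx] + gm * Wv[, t]
    }
    p <- tt$p
    dim(gxpm) <- c(C, tt$Dp, tt$Hp, tt$Wp)
    gx <- gxpm[, (p + 1):(p + D), (p + 1):(p + H), (p + 1):(p + W4),
               drop = FALSE]
    dim(gx) <- d
    if (is.null(b)) list(gx, gW) else list(gx, gW, rowSums(gm))
  })
}

# 2x2x2 max pooling (ties: first window offset in (d, h, w) order wins)
ag_maxpool2 <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  if (any(d[-1] %% 2L != 0L)) {
    stop("ag_maxpool2: spatial dims must be even, got (",
         paste(d[-1], collapse = ", "), ")")
  }
  C <- d[1]; D <- d[2]; H <- d[3]; W <- d[4]
  sd <- seq(1L, D, 2L); sh <- seq(1L, H, 2L); sw <- seq(1L, W, 2L)
  best <- NULL; besto <- NULL
  o <- 0L
  offs <- expand.grid(di = 0:1, hi = 0:1, wi = 0:1)
  for (r in seq_len(nrow(offs))) {
    sub <- xv[, sd + offs$di[r], sh + offs$hi[r], sw + offs$wi[r], drop = FALSE]
    if (is.null(best)) {
      best <- sub; besto <- array(1L, dim(sub))
    } else {
      # NaNs compare to NA; propagate them as maxima so a bad input surfaces
      # as a non-finite loss rather than a subscript error here
      m <- (sub > best) | is.nan(sub)
      m[is.na(m)] <- FALSE
      best[m] <- sub[m]; besto[m] <- r
    }
  }
  ag_op(best, list(x), function(g) {
    gx <- array(0, d)
    for (r in seq_len(nrow(offs))) {
      gsub <- g * (besto == r)
      gx[, sd + offs$di[r], sh + offs$hi[r], sw + offs$wi[r]] <-
        gx[, sd + offs$di[r], sh + offs$hi[r], sw + offs$wi[r],
           drop = FALSE] + gsub
    }
    list(gx)
  })
}

# ---------------------------------------------------------------------------
# trilinear x2 upsampling, corner-agnostic (output centers at i/2 - 1/4 in
# input coordinates, so weights are fixed 3/4 : 1/4 with border clamping)

upsample_axis_indices <- function(L) {
  o <- seq_len(2L * L)
  i <- ceiling(o / 2)
  nb <- ifelse(o %% 2L == 1L, pmax(i - 1L, 1L), pmin(i + 1L, L))
  list(i = i, nb = nb)
}

# move axis `ax` (2..4) of a (C,D,H,W) array to the front, as L x M matrix
axis_front <- function(x, ax) {
  perm <- c(ax, setdiff(1:4, ax))
  xp <- aperm(x, perm)
  d <- dim(xp)
  list(m = matrix(xp, nrow = d[1]), d = d, perm = perm)
}

axis_back <- function(m, d, perm) {
  dim(m) <- d
  aperm(m, order(perm))
}

upsample2_axis_fwd <- function(x, ax) {
  af <- axis_front(x, ax)
  L <- af$d[1]
  ix <- upsample_axis_indices(L)
  out <- 0.75 * af$m[ix$i, , drop = FALSE] + 0.25 * af$m[ix$nb, , drop = FALSE]
  axis_back(out, c(2L * L, af$d[-1]), af$perm)
}

upsample2_axis_bwd <- function(g, ax) {
  af <- axis_front(g, ax)
  L2 <- af$d[1]; L <- L2 %/% 2L
  ix <- upsample_axis_indices(L)
  acc <- matrix(0, L, ncol(af$m))
  a <- rowsum(0.75 * af$m, ix$i)
  acc[as.integer(rownames(a)), ] <- acc[as.integer(rownames(a)), ] + a
  b <- rowsum(0.25 * af$m, ix$nb)
  acc[as.integer(rownames(b)), ] <- acc[as.integer(rownames(b)), ] + b
  axis_back(acc, c(L, af$d[-1]), af$perm)
}

ag_upsample2 <- function(x) {
  xv <- ag_value(x)
  v <- upsample2_axis_fwd(xv, 2L)
  v <- upsample2_axis_fwd(v, 3L)
  v <- upsample2_axis_fwd(v, 4L)
  ag_op(v, list(x), function(g) {
    g <- upsample2_axis_bwd(g, 4L)
    g <- upsample2_axis_bwd(g, 3L)
    g <- upsample2_axis_bwd(g, 2L)
    list(g)
  })
}

# ---------------------------------------------------------------------------
# batch normalization over the spatial axes, per channel; `state` is an
# environment holding running_mean / running_var (EMA, momentum 0.1)

ag_batchnorm <- function(x, gamma, beta, state, training, eps = 1e-5,
                         momentum = 0.1) {
  xv <- ag_value(x)
  d <- dim(xv); C <- d[1]; N <- prod(d[-1])
  xm <- matrix(xv, nrow = C)
  gv <- as.vector(ag_value(gamma)); bv <- as.vector(ag_value(beta))
  if (training) {
    mu <- rowMeans(xm)
    va <- rowMeans(xm * xm) - mu * mu
    va[va < 0] <- 0
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * inv
  out <- xhat * gv + bv
  dim(out) <- d
  ag_op(out, list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = C)
    gxhat <- gm * gv
    if (training) {
      gx <- inv * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
    } else {
      gx <- gxhat * inv
    }
    dim(gx) <- d
    list(gx, rowSums(gm * xhat), rowSums(gm))
  })
}

# channel dropout (whole feature channels are zeroed, inverted scaling);
# identity when not training or rate == 0
ag_dropout_channel <- function(x, rate, training) {
  if (!training || rate <= 0) return(x)
  xv <- ag_value(x)
  d <- dim(xv); C <- d[1]
  keep <- (stats::runif(C) >= rate) / (1 - rate)
  v <- xv * keep
  ag_op(v, list(x), function(g) list(g * keep))
}
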