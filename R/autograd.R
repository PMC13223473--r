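# Package-local state: node counter, grad mode, im2col index cache.
.ns <- new.env(parent = emptyenv())
.ns$counter <- 0L
.ns$grad_enabled <- TRUE
.ns$im2col_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create an autograd tensor node
#'
#' The package executes networks on a small reverse-mode automatic
#' differentiation engine. A node wraps a numeric array (`value`), its
#' `parents` in the computation graph, and a `grad_fn` that maps the node's
#' upstream gradient to a list of gradients, one per parent. Leaf parameters
#' are created with [ag_param()]; most users never build nodes directly.
#'
#' @param value numeric array or vector.
#' @param parents list of parent `ag_tensor` nodes.
#' @param grad_fn function(grad) -> list of parent gradients, or `NULL`.
#' @return an object of class `ag_tensor`.
#' @keywords internal
ag_new <- function(value, parents = list(), grad_fn = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents  # entries may be NULL (non-tracked inputs)
  e$grad_fn <- grad_fn
  e$grad <- NULL
  e$requires <- length(parents) > 0L &&
    any(vapply(parents, function(p) !is.null(p) && isTRUE(p$requires),
               logical(1)))
  .ns$counter <- .ns$counter + 1L
  e$id <- .ns$counter
  class(e) <- "ag_tensor"
  e
}

#' Create a trainable parameter
#' @param value initial numeric array.
#' @return `ag_tensor` leaf with gradient tracking enabled.
#' @keywords internal
ag_param <- function(value) {
  e <- ag_new(value)
  e$requires <- TRUE
  e$is_param <- TRUE
  e
}

is_ag <- function(x) inherits(x, "ag_tensor")

#' Extract the plain array from a tensor or pass an array through
#' @param x `ag_tensor` or numeric array.
#' @keywords internal
ag_value <- function(x) if (is_ag(x)) x$value else x

# Wrap an op result: when gradients are off or no input needs them, return the
# bare array so no graph is retained.
ag_op <- function(value, inputs, grad_fn) {
  # non-ag inputs become NULL parents; grad_fn stays positional over inputs
  parents <- lapply(inputs, function(i) if (is_ag(i)) i else NULL)
  needs <- vapply(parents, function(p) !is.null(p) && isTRUE(p$requires),
                  logical(1))
  if (!.ns$grad_enabled || !any(needs)) return(value)
  ag_new(value, parents = parents, grad_fn = grad_fn)
}

#' Evaluate an expression without building the autograd graph
#'
#' Useful for inference-time forward passes, where retaining the graph would
#' only cost memory.
#'
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_no_grad <- function(expr) {
  old <- .ns$grad_enabled
  .ns$grad_enabled <- FALSE
  on.exit(.ns$grad_enabled <- old)
  expr
}

#' Run reverse-mode backpropagation from a scalar node
#'
#' Accumulates gradients into the `grad` field of every upstream node that
#' requires them (in practice, the parameters created with [ag_param()]).
#'
#' @param root scalar `ag_tensor` (typically a loss value).
#' @param grad seed gradient, defaults to 1.
#' @keywords internal
ag_backward <- function(root, grad = 1) {
  stopifnot(is_ag(root))
  # iterative DFS topological sort (recursion would overflow on deep nets)
  topo <- vector("list", 256L); n_topo <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- fr$node
    key <- as.character(nd$id)
    if (fr$stage == 1L) {
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents) {
        if (!is.null(p) && is.null(visited[[as.character(p$id)]]) &&
            isTRUE(p$requires)) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_topo <- n_topo + 1L
      if (n_topo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[n_topo]] <- nd
    }
  }
  root$grad <- grad
  # topo is child-before-parent reversed already? DFS post-order emits parents
  # first; traverse from the end (root last emitted) backwards.
  for (i in seq(n_topo, 1L)) {
    nd <- topo[[i]]
    if (is.null(nd$grad_fn) || is.null(nd$grad)) next
    gs <- nd$grad_fn(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (is.null(p) || !isTRUE(p$requires) ||
          j > length(gs) || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    if (!isTRUE(nd$is_param)) nd$grad <- NULL  # free intermediate grads
  }
  invisible(root)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# ---------------------------------------------------------------------------
# elementwise primitives

ag_add <- function(x, y) {
  xv <- ag_value(x); yv <- ag_value(y)
  ag_op(xv + yv, list(x, y), function(g) list(g, g))
}

ag_sub <- function(x, y) {
  xv <- ag_value(x); yv <- ag_value(y)
  ag_op(xv - yv, list(x, y), function(g) list(g, -g))
}

ag_mul <- function(x, y) {
  xv <- ag_value(x); yv <- ag_value(y)
  ag_op(xv * yv, list(x, y), function(g) list(g * yv, g * xv))
}

ag_scale <- function(x, a) {
  xv <- ag_value(x)
  ag_op(xv * a, list(x), function(g) list(g * a))
}

ag_relu <- function(x) {
  xv <- ag_value(x)
  v <- xv; v[v < 0] <- 0
  ag_op(v, list(x), function(g) { g[xv <= 0] <- 0; list(g) })
}

ag_sigmoid <- function(x) {
  xv <- ag_value(x)
  s <- stats::plogis(xv)
  if (!is.null(dim(xv))) dim(s) <- dim(xv)
  ag_op(s, list(x), function(g) list(g * s * (1 - s)))
}

# multiply a (C,D,H,W) map by a length-C channel gate (broadcast over voxels)
ag_mul_channel <- function(x, gate) {
  xv <- ag_value(x); gv <- as.vector(ag_value(gate))
  d <- dim(xv); C <- d[1]; N <- prod(d[-1])
  v <- xv * gv  # column-major recycling: gate repeats down channels
  ag_op(v, list(x, gate), function(g) {
    gm <- matrix(g, nrow = C)
    list(g * gv, rowSums(gm * matrix(xv, nrow = C)))
  })
}

# multiply a (C,D,H,W) map by a (1,D,H,W) spatial gate (broadcast over channels)
ag_mul_spatial <- function(x, m) {
  xv <- ag_value(x); mv <- ag_value(m)
  d <- dim(xv); C <- d[1]
  v <- xv * rep(as.vector(mv), each = C)
  dim(v) <- d
  ag_op(v, list(x, m), function(g) {
    gx <- g * rep(as.vector(mv), each = C)
    dim(gx) <- d
    gm <- colSums(matrix(g, nrow = C) * matrix(xv, nrow = C))
    dim(gm) <- c(1, d[-1])
    list(gx, gm)
  })
}

ag_concat_channels <- function(xs) {
  vals <- lapply(xs, ag_value)
  d1 <- dim(vals[[1]])
  Cs <- vapply(vals, function(v) dim(v)[1], numeric(1))
  mats <- lapply(vals, function(v) matrix(v, nrow = dim(v)[1]))
  out <- do.call(rbind, mats)
  dim(out) <- c(sum(Cs), d1[-1])
  ends <- cumsum(Cs); starts <- c(1, utils::head(ends, -1) + 1)
  ag_op(out, xs, function(g) {
    gm <- matrix(g, nrow = sum(Cs))
    lapply(seq_along(xs), function(i) {
      gi <- gm[starts[i]:ends[i], , drop = FALSE]
      dim(gi) <- c(Cs[i], d1[-1])
      gi
    })
  })
}

ag_slice_channels <- function(x, from, to) {
  xv <- ag_value(x)
  d <- dim(xv); C <- d[1]
  xm <- matrix(xv, nrow = C)
  v <- xm[from:to, , drop = FALSE]
  dim(v) <- c(to - from + 1L, d[-1])
  ag_op(v, list(x), function(g) {
    gx <- matrix(0, C, prod(d[-1]))
    gx[from:to, ] <- matrix(g, nrow = to - from + 1L)
    dim(gx) <- d
    list(gx)
  })
}

# mean over all entries -> scalar
ag_mean_all <- function(x) {
  xv <- ag_value(x)
  n <- length(xv)
  ag_op(mean(xv), list(x), function(g) {
    gx <- array(g / n, dim(xv) %||% length(xv))
    list(gx)
  })
}

# ---------------------------------------------------------------------------
# pooling / reductions over the feature-map axes

#' Channel-wise pooling statistics of a feature map
#'
#' Computes the per-voxel mean and maximum across the channel axis of a
#' `(C, D, H, W)` feature map, the two single-channel descriptors that feed
#' spatial attention. Both outputs have shape `(1, D, H, W)`.
#'
#' @param x feature map, a numeric array (or `ag_tensor`) of shape
#'   `(C, D, H, W)` with all entries finite.
#' @return list with elements `avg` and `max`, each of shape `(1, D, H, W)`
#'   (plain arrays when `x` is a plain array, graph nodes otherwise).
#' @examples
#' x <- array(rnorm(2 * 2 * 3 * 3), c(2, 2, 3, 3))
#' s <- channel_pool_stats(x)
#' dim(s$avg)  # 1 2 3 3
#' @export
channel_pool_stats <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  if (is.null(d) || length(d) != 4L || d[1] < 1L) {
    stop("channel_pool_stats: input must be a (C, D, H, W) array with C >= 1")
  }
  if (!all(is.finite(xv))) stop("channel_pool_stats: input must be finite")
  C <- d[1]; N <- prod(d[-1])
  xm <- matrix(xv, nrow = C)
  avg <- colMeans(xm); dim(avg) <- c(1, d[-1])
  if (C == 1L) {
    jmax <- rep(1L, N)
    mx <- as.vector(xm)
  } else {
    tm <- t(xm)
    jmax <- max.col(tm, ties.method = "first")
    mx <- xm[cbind(jmax, seq_len(N))]
  }
  dim(mx) <- c(1, d[-1])
  avg_node <- ag_op(avg, list(x), function(g) {
    gx <- matrix(rep(as.vector(g) / C, each = C), nrow = C)
    dim(gx) <- d
    list(gx)
  })
  max_node <- ag_op(mx, list(x), function(g) {
    gx <- matrix(0, C, N)
    gx[cbind(jmax, seq_len(N))] <- as.vector(g)
    dim(gx) <- d
    list(gx)
  })
  list(avg = avg_node, max = max_node)
}

# global average pool over (D,H,W): (C,D,H,W) -> length-C vector
ag_gap <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv); C <- d[1]; N <- prod(d[-1])
  v <- rowMeans(matrix(xv, nrow = C))
  ag_op(v, list(x), function(g) {
    gx <- matrix(as.vector(g) / N, C, N)
    dim(gx) <- d
    list(gx)
  })
}

# global max pool over (D,H,W): (C,D,H,W) -> length-C vector
ag_gmp <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv); C <- d[1]; N <- prod(d[-1])
  xm <- matrix(xv, nrow = C)
  j <- max.col(xm, ties.method = "first")
  v <- xm[cbind(seq_len(C), j)]
  ag_op(v, list(x), function(g) {
    gx <- matrix(0, C, N)
    gx[cbind(seq_len(C), j)] <- as.vector(g)
    dim(gx) <- d
    list(gx)
  })
}

# ---------------------------------------------------------------------------
# dense / 1-D ops on channel descriptors

# v: length-n vector; W: n x m; b: length m
ag_dense <- function(v, W, b = NULL) {
  vv <- as.vector(ag_value(v)); Wv <- ag_value(W)
  out <- as.vector(crossprod(Wv, vv))
  if (!is.null(b)) out <- out + as.vector(ag_value(b))
  inputs <- list(v, W)
  if (!is.null(b)) inputs <- c(inputs, list(b))
  ag_op(out, inputs, function(g) {
    g <- as.vector(g)
    gv <- as.vector(Wv %*% g)
    gW <- outer(vv, g)
    if (is.null(b)) list(gv, gW) else list(gv, gW, g)
  })
}

# same-padded 1-D convolution along the channel axis (single filter, no bias):
# used by efficient channel attention for local cross-channel interaction
ag_conv1d_channels <- function(v, w) {
  vv <- as.vector(ag_value(v)); wv <- as.vector(ag_value(w))
  C <- length(vv); k <- length(wv); p <- (k - 1L) %/% 2L
  vp <- c(rep(0, p), vv, rep(0, p))
  out <- numeric(C)
  for (j in seq_len(k)) out <- out + wv[j] * vp[j:(j + C - 1L)]
  ag_op(out, list(v, w), function(g) {
    g <- as.vector(g)
    gw <- vapply(seq_len(k), function(j) sum(g * vp[j:(j + C - 1L)]), numeric(1))
    gvp <- numeric(C + 2L * p)
    for (j in seq_len(k)) {
      idx <- j:(j + C - 1L)
      gvp[idx] <- gvp[idx] + wv[j] * g
    }
    list(gvp[(p + 1L):(p + C)], gw)
  })
}
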