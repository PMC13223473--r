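# Layer objects: plain lists of ag_param tensors plus static config.
# Mutable state (BatchNorm running statistics) lives in a nested environment
# so it survives list copying.

#' Forward pass through a layer or model
#' @param object a layer or model object.
#' @param x input feature map (array or `ag_tensor`).
#' @param ... passed on to methods (e.g. `training = TRUE`).
#' @return the transformed feature map.
#' @export
forward <- function(object, x, ...) UseMethod("forward")

#' Collect the trainable parameters of a layer or model
#' @param object a layer or model object.
#' @param prefix name prefix used for nested modules.
#' @return named list of `ag_tensor` parameters.
#' @export
parameters <- function(object, prefix = "") UseMethod("parameters")

#' @export
parameters.default <- function(object, prefix = "") list()

collect_params <- function(prefix, items) {
  out <- list()
  for (nm in names(items)) {
    it <- items[[nm]]
    if (is_ag(it)) {
      out[[paste0(prefix, nm)]] <- it
    } else if (!is.null(it)) {
      out <- c(out, parameters(it, prefix = paste0(prefix, nm, ".")))
    }
  }
  out
}

he_init <- function(n, fan_in) {
  stats::rnorm(n, sd = sqrt(2 / fan_in))
}

# --- conv3d ----------------------------------------------------------------

conv3d_layer <- function(in_ch, out_ch, k = 3L, dilation = 1L, bias = TRUE,
                         zero_init = FALSE) {
  if (k %% 2L != 1L) stop("conv3d_layer: kernel size must be odd, got ", k)
  n <- in_ch * k^3
  Wv <- if (zero_init) matrix(0, n, out_ch) else
    matrix(he_init(n * out_ch, n), n, out_ch)
  structure(list(
    W = ag_param(Wv),
    b = if (bias) ag_param(numeric(out_ch)) else NULL,
    k = as.integer(k), dilation = as.integer(dilation),
    in_ch = in_ch, out_ch = out_ch
  ), class = "conv3d_layer")
}

#' @export
forward.conv3d_layer <- function(object, x, ...) {
  xv <- ag_value(x)
  if (dim(xv)[1] != object$in_ch) {
    stop("conv3d_layer: expected ", object$in_ch, " input channels, got ",
         dim(xv)[1])
  }
  if (object$k == 1L && object$dilation == 1L) {
    W1 <- object$W
    # 1x1x1 kernels use the fast pointwise path; weight rows are already
    # channel-ordered because k^3 == 1
    return(ag_pointwise(x, W1, object$b))
  }
  ag_conv3d(x, object$W, object$b, object$k, object$dilation)
}

#' @export
parameters.conv3d_layer <- function(object, prefix = "") {
  collect_params(prefix, list(W = object$W, b = object$b))
}

# --- pointwise / dense -----------------------------------------------------

dense_layer <- function(in_n, out_n, bias = TRUE, zero_init = FALSE) {
  Wv <- if (zero_init) matrix(0, in_n, out_n) else
    matrix(he_init(in_n * out_n, in_n), in_n, out_n)
  structure(list(
    W = ag_param(Wv),
    b = if (bias) ag_param(numeric(out_n)) else NULL,
    in_n = in_n, out_n = out_n
  ), class = "dense_layer")
}

#' @export
forward.dense_layer <- function(object, x, ...) {
  ag_dense(x, object$W, object$b)
}

#' @export
parameters.dense_layer <- function(object, prefix = "") {
  collect_params(prefix, list(W = object$W, b = object$b))
}

# --- batchnorm -------------------------------------------------------------

batchnorm3d <- function(ch, eps = 1e-5, momentum = 0.1) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(ch)
  st$running_var <- rep(1, ch)
  structure(list(
    gamma = ag_param(rep(1, ch)),
    beta = ag_param(numeric(ch)),
    state = st, ch = ch, eps = eps, momentum = momentum
  ), class = "batchnorm3d")
}

#' @export
forward.batchnorm3d <- function(object, x, training = FALSE, ...) {
  ag_batchnorm(x, object$gamma, object$beta, object$state, training,
               eps = object$eps, momentum = object$momentum)
}

#' @export
parameters.batchnorm3d <- function(object, prefix = "") {
  collect_params(prefix, list(gamma = object$gamma, beta = object$beta))
}

# --- depthwise-separable convolution ---------------------------------------
# depthwise (per-channel, dilated, k^3, same-padding) followed by a
# pointwise 1x1x1 mixing convolution; biases on both

sepconv3d_layer <- function(ch, k, dilation = 1L) {
  structure(list(
    dw_W = ag_param(matrix(he_init(ch * k^3, k^3), ch, k^3)),
    dw_b = ag_param(numeric(ch)),
    pw_W = ag_param(matrix(he_init(ch * ch, ch), ch, ch)),
    pw_b = ag_param(numeric(ch)),
    k = as.integer(k), dilation = as.integer(dilation), ch = ch
  ), class = "sepconv3d_layer")
}

#' @export
forward.sepconv3d_layer <- function(object, x, ...) {
  y <- ag_depthwise(x, object$dw_W, object$dw_b, object$k, object$dilation)
  ag_pointwise(y, object$pw_W, object$pw_b)
}

#' @export
parameters.sepconv3d_layer <- function(object, prefix = "") {
  collect_params(prefix, list(dw_W = object$dw_W, dw_b = object$dw_b,
                              pw_W = object$pw_W, pw_b = object$pw_b))
}

# --- parameter state I/O ---------------------------------------------------

# snapshot all parameter values plus batchnorm running stats as plain arrays
module_state <- function(object) {
  ps <- parameters(object)
  vals <- lapply(ps, function(p) p$value)
  bn <- bn_states(object)
  list(params = vals,
       bn = lapply(bn, function(st) list(mean = st$running_mean,
                                         var = st$running_var)))
}

load_module_state <- function(object, state) {
  ps <- parameters(object)
  stopifnot(setequal(names(ps), names(state$params)))
  for (nm in names(ps)) ps[[nm]]$value <- state$params[[nm]]
  bn <- bn_states(object)
  stopifnot(length(bn) == length(state$bn))
  for (i in seq_along(bn)) {
    bn[[i]]$running_mean <- state$bn[[i]]$mean
    bn[[i]]$running_var <- state$bn[[i]]$var
  }
  invisible(object)
}

# recursively find batchnorm state environments (stable order)
bn_states <- function(object) {
  if (inherits(object, "batchnorm3d")) return(list(object$state))
  if (is.list(object) && !is_ag(object)) {
    out <- list()
    for (it in object) {
      if (is.list(it) || inherits(it, "batchnorm3d")) {
        out <- c(out, bn_states(it))
      }
    }
    return(out)
  }
  list()
}
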