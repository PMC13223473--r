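# Engine correctness: vectorized convolution and structural ops against
# naive nested-loop oracles and finite differences.

test_that("conv3d forward matches the naive oracle (k = 3 and dilated)", {
  set.seed(1)
  for (spec in list(list(cin = 3, cout = 2, k = 3, dil = 1, d = c(4, 6, 5)),
                    list(cin = 2, cout = 1, k = 3, dil = 2, d = c(5, 5, 5)),
                    list(cin = 2, cout = 1, k = 7, dil = 1, d = c(4, 8, 8)))) {
    x <- rand_arr(spec$cin, spec$d[1], spec$d[2], spec$d[3])
    Wm <- matrix(rnorm(spec$cin * spec$k^3 * spec$cout), ncol = spec$cout)
    b <- rnorm(spec$cout)
    got <- conv3d_forward(x, Wm, b, spec$k, spec$dil)
    want <- naive_conv3d(x, Wm, b, spec$k, spec$dil)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("conv3d gradients match finite differences", {
  set.seed(2)
  x0 <- rand_arr(2, 4, 4, 4)
  W0 <- matrix(rnorm(2 * 27 * 2), ncol = 2)
  b0 <- rnorm(2)
  target <- (rand_arr(2, 4, 4, 4) > 0) * 1
  loss_of <- function(xv, Wv, bv) {
    out <- conv3d_forward(xv, Wv, bv, 3L, 1L)
    seg_loss_with_grad(out, target)$loss
  }
  xp <- ag_param(x0); Wp <- ag_param(W0); bp <- ag_param(b0)
  loss <- ag_seg_loss(ag_conv3d(xp, Wp, bp, 3L, 1L), target)
  ag_backward(loss)
  idx <- c(1, 17, 63, 128)
  fx <- fd_grad(function(v) loss_of(v, W0, b0), x0, idx)
  expect_lt(max(abs(fx - xp$grad[idx])), 1e-7)
  iw <- c(2, 30, 55, 100)
  fw <- fd_grad(function(v) loss_of(x0, v, b0), W0, iw)
  expect_lt(max(abs(fw - Wp$grad[iw])), 1e-7)
  fb <- fd_grad(function(v) loss_of(x0, W0, v), b0, 1:2)
  expect_lt(max(abs(fb - bp$grad[1:2])), 1e-7)
})

test_that("depthwise-separable convolution matches the composed oracle", {
  set.seed(3)
  layer <- sepconv3d_layer(4L, 3L, dilation = 2L)
  x <- rand_arr(4, 4, 5, 5)
  got <- ag_value(forward(layer, x))
  dw <- naive_depthwise(x, ag_value(layer$dw_W),
                        as.vector(ag_value(layer$dw_b)), 3L, 2L)
  pw <- ag_value(layer$pw_W); pb <- as.vector(ag_value(layer$pw_b))
  want <- array(0, dim(x))
  for (dd in 1:4) for (hh in 1:5) for (ww in 1:5) {
    want[, dd, hh, ww] <- t(pw) %*% dw[, dd, hh, ww] + pb
  }
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("maxpool halves spatial dims and routes gradient to the argmax", {
  x0 <- array(0, c(1, 2, 2, 2))
  x0[1, , , ] <- 1:8
  xp <- ag_param(x0)
  out <- ag_maxpool2(xp)
  expect_equal(dim(ag_value(out)), c(1, 1, 1, 1))
  expect_equal(as.vector(ag_value(out)), 8)
  ag_backward(ag_mean_all(out))
  expect_equal(sum(xp$grad != 0), 1)
  expect_equal(xp$grad[1, 2, 2, 2], 1)
  expect_error(ag_maxpool2(rand_arr(1, 3, 4, 4)), "even")
})

test_that("trilinear x2 upsampling doubles dims and preserves constants", {
  x <- array(2.5, c(3, 2, 4, 4))
  up <- ag_value(ag_upsample2(x))
  expect_equal(dim(up), c(3, 4, 8, 8))
  expect_equal(max(abs(up - 2.5)), 0)
  # interior output samples mix neighbors 3:1
  y <- array(0, c(1, 2, 2, 2)); y[1, , 1, 1] <- c(0, 4)
  u <- ag_value(ag_upsample2(y))
  expect_equal(u[1, 2, 1, 1], 0.75 * 0 + 0.25 * 4)
  expect_equal(u[1, 3, 1, 1], 0.75 * 4 + 0.25 * 0)
})

test_that("upsample gradient matches finite differences", {
  set.seed(4)
  x0 <- rand_arr(2, 2, 4, 4)
  w <- rand_arr(2, 4, 8, 8)
  f <- function(v) sum(ag_value(ag_upsample2(v)) * w)
  xp <- ag_param(x0)
  out <- ag_upsample2(xp)
  loss <- ag_mean_all(ag_mul(out, w))
  ag_backward(loss, grad = length(w))
  idx <- c(1, 9, 33, 64)
  expect_lt(max(abs(fd_grad(f, x0, idx) - xp$grad[idx])), 1e-6)
})

test_that("batchnorm normalizes per channel and tracks running stats", {
  set.seed(5)
  bn <- batchnorm3d(3L)
  x <- rand_arr(3, 2, 4, 4) * 2 + 5
  out <- ag_value(forward(bn, x, training = TRUE))
  m <- apply(out, 1, mean); v <- apply(out, 1, stats::var)
  expect_lt(max(abs(m)), 1e-10)
  expect_lt(max(abs(v - 1)), 0.05            # biased vs unbiased variance
  )
  expect_lt(max(abs(bn$state$running_mean - 0.1 * apply(x, 1, mean))), 1e-10)
  # eval mode uses running stats, not batch stats
  out2 <- ag_value(forward(bn, x, training = FALSE))
  expect_gt(max(abs(apply(out2, 1, mean))), 0.1)
})

test_that("channel_pool_stats returns per-voxel channel mean and max", {
  set.seed(6)
  x <- rand_arr(4, 2, 3, 3)
  st <- channel_pool_stats(x)
  expect_equal(dim(st$avg), c(1, 2, 3, 3))
  expect_equal(st$avg[1, , , ], apply(x, 2:4, mean))
  expect_equal(st$max[1, , , ], apply(x, 2:4, max))
  expect_error(channel_pool_stats(array(1, c(3, 3))), "C, D, H, W")
})
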