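# Attention blocks: oracle equivalence, gate ranges, adaptive kernel size.

test_that("dynamic_kernel_size reproduces the worked examples", {
  expect_identical(dynamic_kernel_size(512), 5L)
  expect_identical(dynamic_kernel_size(256), 5L)
  expect_identical(dynamic_kernel_size(128), 5L)
  expect_identical(dynamic_kernel_size(64), 3L)
  expect_identical(dynamic_kernel_size(4), 1L)
  expect_identical(dynamic_kernel_size(1), 1L)   # floored at 1
  # exact tie between two odd integers rounds up
  expect_identical(dynamic_kernel_size(2^7), 5L) # t = 4 midway 3 and 5
  expect_error(dynamic_kernel_size(0), ">= 1")
  expect_error(dynamic_kernel_size(8, gamma = 0), "gamma")
})

test_that("spatial attention matches the naive oracle", {
  set.seed(11)
  blk <- spatial_attention_block(7L)
  x <- rand_arr(8, 4, 8, 8)
  got <- ag_value(forward(blk, x))
  expect_lt(max(abs(got - naive_sa(blk, x))), 1e-5)
})

test_that("spatial attention gate is sigmoid-bounded and 0.5 at zero weights", {
  set.seed(12)
  blk <- spatial_attention_block(3L)
  blk$conv$W$value[] <- 0
  blk$conv$b$value[] <- 0
  x <- rand_arr(3, 2, 4, 4)
  res <- forward(blk, x, with_gate = TRUE)
  g <- ag_value(res$gate)
  expect_true(all(g == 0.5))
  expect_equal(ag_value(res$output), 0.5 * x)
  expect_error(spatial_attention_block(4L), "odd")
})

test_that("dilated ECA matches the naive oracle", {
  set.seed(13)
  blk <- dilated_eca_block(8L)
  x <- rand_arr(8, 4, 8, 8)
  got <- ag_value(forward(blk, x))
  expect_lt(max(abs(got - naive_eca(blk, x))), 1e-5)
})

test_that("dilated ECA gate lies in [0.5, 1) and channels must split by 4", {
  set.seed(14)
  blk <- dilated_eca_block(8L)
  x <- rand_arr(8, 4, 4, 4)
  res <- forward(blk, x, with_gate = TRUE)
  g <- as.vector(ag_value(res$gate))
  expect_true(all(g >= 0.5 & g < 1))
  expect_error(dilated_multiscale_block(6L), "divisible")
})

test_that("dilated multi-scale block preserves shape at all rates", {
  set.seed(15)
  blk <- dilated_multiscale_block(8L, rates = c(1L, 2L, 5L, 7L), kernel = 3L)
  x <- rand_arr(8, 4, 8, 8)
  expect_equal(dim(ag_value(forward(blk, x))), dim(x))
})

test_that("CBAM matches the naive oracle in both gate modes", {
  set.seed(16)
  for (mode in c("summed_logits", "per_branch_sigmoid")) {
    blk <- cbam_block(8L, reduction = 4L, kernel = 7L, gate_mode = mode)
    x <- rand_arr(8, 4, 8, 8)
    got <- ag_value(forward(blk, x))
    expect_lt(max(abs(got - naive_cbam(blk, x))), 1e-5)
  }
})

test_that("CBAM gate ranges follow the gate mode", {
  set.seed(17)
  x <- rand_arr(16, 2, 4, 4)
  b1 <- cbam_block(16L, reduction = 4L, gate_mode = "summed_logits")
  r1 <- forward(b1, x, with_gate = TRUE)
  g1 <- as.vector(ag_value(r1$channel_gate))
  expect_true(all(g1 > 0 & g1 < 1))
  b2 <- cbam_block(16L, reduction = 4L, gate_mode = "per_branch_sigmoid")
  r2 <- forward(b2, x, with_gate = TRUE)
  g2 <- as.vector(ag_value(r2$channel_gate))
  expect_true(all(g2 > 0 & g2 < 2))
  expect_error(cbam_block(8L, reduction = 16L), "reduction")
  expect_error(cbam_block(16L, kernel = 4L), "odd")
})

test_that("SE matches the naive oracle and gates per channel in (0, 1)", {
  set.seed(18)
  blk <- se_block(8L, reduction = 4L)
  x <- rand_arr(8, 4, 8, 8)
  got <- ag_value(forward(blk, x))
  expect_lt(max(abs(got - naive_se(blk, x))), 1e-5)
  res <- forward(blk, x, with_gate = TRUE)
  g <- as.vector(ag_value(res$gate))
  expect_length(g, 8)
  expect_true(all(g > 0 & g < 1))
  # hidden width floors at 1
  tiny <- se_block(2L, reduction = 16L)
  expect_equal(tiny$fc1$out_n, 1L)
})

test_that("attention blocks are shape-preserving", {
  set.seed(19)
  x <- rand_arr(8, 2, 4, 4)
  for (blk in list(spatial_attention_block(3L), dilated_eca_block(8L),
                   cbam_block(8L, reduction = 4L), se_block(8L, 4L))) {
    expect_equal(dim(ag_value(forward(blk, x))), dim(x))
  }
})
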