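# Training loop, schedule, augmentation, evaluation, significance test.

tiny_pairs <- function(n, seed, shape = c(8L, 16L, 16L)) {
  generate_patches(phantom_config(n_patches = n, patch_shape = shape,
                                  diameter_range = c(3, 8),
                                  fraction_empty = 0, seed = seed))$pairs
}

tiny_model_cfg <- function(variant = "enhanced") {
  unet3d_config(variant, base_channels = 4L, cbam_reduction = 4L,
                se_reduction = 4L)
}

test_that("the lr schedule is exactly linear and nonnegative", {
  cfg <- train_config(epochs = 10L)
  lrs <- vapply(1:10, lr_schedule, numeric(1), cfg = cfg)
  expect_equal(lrs[1], cfg$lr0)
  expect_true(all(diff(lrs) < 0))
  expect_true(all(lrs >= 0))
  # lr(t)/lr0 + t/epochs == 1 at every epoch boundary (t 0-based)
  t0 <- 0:9
  expect_equal(lrs / cfg$lr0 + t0 / 10, rep(1, 10))
  expect_error(train_config(epochs = 0), "epochs")
})

test_that("augmentation switches off to identity and flips are involutions", {
  set.seed(61)
  pair <- tiny_pairs(1, 1)[[1]]
  off <- train_config(augment_flip = FALSE, augment_rotate = FALSE,
                      augment_noise = FALSE)
  expect_identical(augment(pair, off), pair)
  for (ax in 1:3) {
    expect_identical(flip_axis3(flip_axis3(pair$image, ax), ax), pair$image)
  }
  expect_identical(rotate_inplane(pair$image, 4L), pair$image)
})

test_that("geometric augmentation preserves the mask voxel count", {
  set.seed(62)
  pair <- tiny_pairs(1, 2)[[1]]
  cfg <- train_config(augment_noise = FALSE)
  for (i in 1:10) {
    a <- augment(pair, cfg)
    expect_equal(sum(a$mask), sum(pair$mask))
    expect_true(all(a$mask %in% c(0, 1)))
  }
})

test_that("noise augmentation touches the image only", {
  set.seed(63)
  pair <- tiny_pairs(1, 3)[[1]]
  cfg <- train_config(augment_flip = FALSE, augment_rotate = FALSE,
                      noise_sigma = 0.05)
  a <- augment(pair, cfg)
  expect_identical(a$mask, pair$mask)
  expect_gt(max(abs(a$image - pair$image)), 0)
})

test_that("3 epochs on 16 patches yield 3 history rows with decreasing lr", {
  tr <- tiny_pairs(16, 4)
  va <- tiny_pairs(4, 5)
  res <- train(tiny_model_cfg(), tr, va,
               train_config(epochs = 3L, batch_size = 4L, seed = 1))
  expect_equal(nrow(res$history), 3L)
  expect_equal(res$history$epoch, 1:3)
  expect_true(all(diff(res$history$lr) < 0))
  expect_equal(names(res$history),
               c("epoch", "train_loss", "val_DSC", "val_SEN", "val_PPV",
                 "lr"))
  expect_equal(res$best_val_dice, max(res$history$val_DSC))
})

test_that("identical seeds give identical final weights", {
  tr <- tiny_pairs(8, 6)
  va <- tiny_pairs(2, 7)
  cfg <- train_config(epochs = 2L, batch_size = 4L, seed = 9)
  r1 <- train(tiny_model_cfg("baseline"), tr, va, cfg)
  r2 <- train(tiny_model_cfg("baseline"), tr, va, cfg)
  p1 <- parameters(r1$model); p2 <- parameters(r2$model)
  expect_true(all(mapply(function(a, b) identical(a$value, b$value),
                         p1, p2)))
})

test_that("a non-finite loss aborts naming the batch", {
  tr <- tiny_pairs(4, 8)
  tr[[2]]$image[1] <- NaN
  va <- tiny_pairs(2, 9)
  cfg <- train_config(epochs = 1L, batch_size = 4L, seed = 1,
                      augment_flip = FALSE, augment_rotate = FALSE,
                      augment_noise = FALSE)
  expect_error(train(tiny_model_cfg("baseline"), tr, va, cfg),
               "non-finite loss at epoch 1, batch")
  expect_error(train(tiny_model_cfg(), list(), va, cfg), "nonempty")
})

test_that("history and checkpoint files are written when requested", {
  tr <- tiny_pairs(4, 10)
  va <- tiny_pairs(2, 11)
  hp <- tempfile(fileext = ".csv"); cp <- tempfile(fileext = ".rds")
  res <- train(tiny_model_cfg("baseline"), tr, va,
               train_config(epochs = 2L, seed = 2),
               checkpoint_path = cp, history_path = hp)
  expect_true(file.exists(hp) && file.exists(cp))
  ck <- load_checkpoint(cp)
  expect_equal(ck$meta$best_val_dice, res$best_val_dice)
  ev1 <- evaluate(res$model, va)
  ev2 <- evaluate(ck$model, va)
  expect_identical(ev1$macro, ev2$macro)   # bit-wise restore
})

# an oracle model stub: predicts positive wherever the image exceeds 0.5
forward.oracle_stub <- function(object, x, ...) (ag_value(x) - 0.5) * 1e3
registerS3method("forward", "oracle_stub", forward.oracle_stub,
                 envir = asNamespace("nodseg3d"))

test_that("evaluate matches hand-averaged per-volume metrics", {
  set.seed(64)
  stub <- structure(list(), class = "oracle_stub")
  ds <- lapply(1:3, function(i) {
    img <- array(runif(8 * 8 * 8), c(8, 8, 8))
    list(image = img, mask = (img > 0.5) * 1)
  })
  ev <- evaluate(stub, ds)
  expect_equal(unname(ev$macro), c(1, 1, 1))   # oracle model is perfect
  # constant-zero model scores zero Dice on nonempty masks
  zero_stub <- structure(list(), class = "zero_stub")
  forward.zero_stub <- function(object, x, ...) ag_value(x) * 0 - 10
  registerS3method("forward", "zero_stub", forward.zero_stub,
                   envir = asNamespace("nodseg3d"))
  ev0 <- evaluate(zero_stub, ds)
  expect_equal(ev0$macro[["dsc"]], 0)
  # macro average equals the hand average of the table
  expect_equal(ev0$macro[["sen"]], mean(ev0$per_volume$sen))
  expect_error(evaluate(stub, list()), "empty")
})

test_that("paired t-test matches hand arithmetic and conventions", {
  r <- paired_t_test(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$mean_diff, 2)
  expect_true(r$ci95[1] <= r$mean_diff && r$mean_diff <= r$ci95[2])
  same <- paired_t_test(c(1, 2), c(1, 2))
  expect_equal(same$t, 0)
  expect_warning(zv <- paired_t_test(c(2, 3), c(1, 2)), "zero variance")
  expect_identical(zv$t, Inf)
  expect_equal(zv$mean_diff, 1)
})

test_that("ablation_run produces one row per variant", {
  tr <- tiny_pairs(4, 12)
  va <- tiny_pairs(2, 13)
  tab <- ablation_run(c("baseline", "sa"), tr, va,
                      train_config(epochs = 1L, seed = 3),
                      base_channels = 4L, cbam_reduction = 4L,
                      se_reduction = 4L)
  expect_equal(tab$variant, c("baseline", "sa"))
  expect_gt(tab$params[2], tab$params[1])
})

test_that("the optimizer comparison emits the three-optimizer report", {
  tr <- tiny_pairs(4, 14)
  va <- tiny_pairs(2, 15)
  tab <- compare_optimizers(tiny_model_cfg("baseline"), tr, va,
                            train_config(epochs = 1L, seed = 4))
  expect_equal(tab$optimizer, c("adam", "adamw", "radam"))
  expect_equal(names(tab), c("optimizer", "dice", "f1",
                             "mean_epoch_seconds"))
  expect_true(all(is.finite(tab$dice)))
})

test_that("decoupled weight decay shrinks weights even at zero gradient", {
  p <- ag_param(matrix(1, 2, 2))
  p$grad <- matrix(0, 2, 2)
  st <- optimizer_state(list(p), train_config(optimizer = "adamw",
                                              weight_decay = 0.1))
  optimizer_step(st, list(p), lr = 0.5)
  expect_equal(unique(as.vector(p$value)), 1 - 0.5 * 0.1 * 1)
})

test_that("a short PSO over a 1-epoch phantom training completes", {
  tr <- tiny_pairs(4, 16)
  va <- tiny_pairs(2, 17)
  fit <- make_dice_fitness(tiny_model_cfg("baseline"), tr, va,
                           train_config(epochs = 1L, seed = 5))
  cfg <- swarm_config(n_pop = 2, max_iter = 1, seed = 1)
  r <- run_pso(fit, cfg)
  expect_true(is.finite(r$best_fitness))
  expect_lte(r$best_fitness, 0)   # negative validation Dice
})
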