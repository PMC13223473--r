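# Training loop, optimizers, augmentation, evaluation, optimizer comparison,
# ablation harness and the paired significance test.

#' Training configuration
#'
#' Defaults follow the full-scale recipe (200 epochs, batch 4, initial
#' learning rate 1e-3 decayed linearly, AdamW with weight decay 5.17e-4);
#' scale `epochs` and the dataset down for CPU runs.
#'
#' @param epochs number of epochs (>= 1).
#' @param batch_size samples per optimizer step (gradient accumulation).
#' @param lr0 initial learning rate; the rate entering epoch `t` (1-based)
#'   is `lr0 * (1 - (t - 1) / epochs)`, exactly linear and nonnegative.
#' @param optimizer one of `"adamw"`, `"adam"`, `"radam"`.
#' @param weight_decay L2 / decoupled weight-decay coefficient.
#' @param loss a [loss_weights()] configuration.
#' @param augment_flip,augment_rotate,augment_noise augmentation switches.
#' @param noise_sigma augmentation noise level (image only).
#' @param seed seed covering weight init, data order and augmentation.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 200L, batch_size = 4L, lr0 = 1e-3,
                         optimizer = c("adamw", "adam", "radam"),
                         weight_decay = 5.17e-4,
                         loss = loss_weights(),
                         augment_flip = TRUE, augment_rotate = TRUE,
                         augment_noise = TRUE, noise_sigma = 0.01,
                         seed = 0L) {
  optimizer <- match.arg(optimizer)
  if (epochs < 1L) stop("train_config: epochs must be >= 1")
  stopifnot(batch_size >= 1L, lr0 > 0, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 optimizer = optimizer, weight_decay = weight_decay,
                 loss = loss, augment_flip = augment_flip,
                 augment_rotate = augment_rotate,
                 augment_noise = augment_noise, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' @param t 1-based epoch index.
#' @param cfg a [train_config()].
#' @return the (exactly linear) learning rate entering epoch `t`.
#' @export
lr_schedule <- function(t, cfg) {
  cfg$lr0 * (1 - (t - 1) / cfg$epochs)
}

flip_axis3 <- function(a, ax) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[ax]] <- rev(seq_len(dim(a)[ax]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

rotate_inplane <- function(a, k) {
  k <- k %% 4L
  if (k == 0L) return(a)
  d <- dim(a)
  if (d[2] != d[3] && k %% 2L == 1L) return(a)  # non-square plane: skip 90s
  for (i in seq_len(k)) {
    a <- aperm(a, c(1, 3, 2))
    a <- flip_axis3(a, 2L)
  }
  a
}

#' Augment a patch pair
#'
#' Random flips along each spatial axis (p = 0.5 each) and a random in-plane
#' 90-degree rotation are applied identically to image and mask; Gaussian
#' noise goes on the image only, so the mask stays binary. Rotation is
#' restricted to in-plane multiples of 90 degrees because the anisotropic
#' z-axis makes arbitrary 3-D rotations ill-defined. Consumes the global RNG.
#'
#' @param pair list with `image` and `mask` arrays, `(z, y, x)`.
#' @param cfg a [train_config()].
#' @return augmented pair.
#' @export
augment <- function(pair, cfg = train_config()) {
  img <- pair$image; msk <- pair$mask
  if (cfg$augment_flip) {
    for (ax in 1:3) {
      if (stats::runif(1) < 0.5) {
        img <- flip_axis3(img, ax); msk <- flip_axis3(msk, ax)
      }
    }
  }
  if (cfg$augment_rotate) {
    k <- sample(0:3, 1)
    img <- rotate_inplane(img, k); msk <- rotate_inplane(msk, k)
  }
  if (cfg$augment_noise && cfg$noise_sigma > 0) {
    img <- img + cfg$noise_sigma * array(stats::rnorm(length(img)), dim(img))
  }
  pair$image <- img; pair$mask <- msk
  pair
}

# ---------------------------------------------------------------------------
# optimizers: Adam (L2 in-gradient), AdamW (decoupled decay), RAdam
# (rectified moment estimate; L2 in-gradient)

optimizer_state <- function(params, cfg) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim(p$value) %||%
                                              length(p$value))),
       v = lapply(params, function(p) array(0, dim(p$value) %||%
                                              length(p$value))),
       cfg = cfg)
}

optimizer_step <- function(state, params, lr) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  t <- state$t
  cfg <- state$cfg
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (cfg$optimizer != "adamw" && cfg$weight_decay > 0) {
      g <- g + cfg$weight_decay * p$value
    }
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g * g
    mhat <- state$m[[i]] / (1 - b1^t)
    if (cfg$optimizer == "radam") {
      rho_inf <- 2 / (1 - b2) - 1
      rho_t <- rho_inf - 2 * t * b2^t / (1 - b2^t)
      if (rho_t > 4) {
        vhat <- sqrt(state$v[[i]] / (1 - b2^t))
        r_t <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                      ((rho_inf - 4) * (rho_inf - 2) * rho_t))
        upd <- lr * r_t * mhat / (vhat + eps)
      } else {
        upd <- lr * mhat
      }
    } else {
      vhat <- sqrt(state$v[[i]] / (1 - b2^t))
      upd <- lr * mhat / (vhat + eps)
    }
    if (cfg$optimizer == "adamw" && cfg$weight_decay > 0) {
      upd <- upd + lr * cfg$weight_decay * p$value
    }
    p$value <- p$value - upd
  }
  state
}

as_model_input <- function(image) {
  x <- image
  dim(x) <- c(1L, dim(image))
  x
}

#' Voxelwise nodule probabilities for a single patch
#'
#' Runs a no-gradient forward pass and applies the logistic link.
#'
#' @param model a trained `unet3d` model.
#' @param image a `(D, H, W)` image array.
#' @return array of probabilities with the same shape as `image`.
#' @export
predict_prob <- function(model, image) {
  logits <- with_no_grad(forward(model, as_model_input(image),
                                 training = FALSE))
  p <- stats::plogis(ag_value(logits))
  dim(p) <- dim(image)
  p
}

#' Train a segmentation model
#'
#' Runs the seeded loop: per epoch, samples are shuffled, augmented and
#' consumed in gradient-accumulation batches of `cfg$batch_size`; the
#' learning rate follows [lr_schedule()]; validation runs after every epoch
#' and the weights with the highest validation Dice are kept (and written to
#' `checkpoint_path` when given). The run is fully determined by
#' `cfg$seed` when `model` is passed as a [unet3d_config()] (weights are
#' then initialized after seeding).
#'
#' @param model a built `unet3d` or a [unet3d_config()].
#' @param train_set,val_set nonempty lists of pairs with `image` and `mask`.
#' @param cfg a [train_config()].
#' @param checkpoint_path optional path for the best-epoch checkpoint.
#' @param history_path optional path for the history CSV.
#' @param verbose print one line per epoch.
#' @return list with `history` (epoch, train_loss, val_DSC, val_SEN,
#'   val_PPV, lr), `best_epoch`, `best_val_dice`, the trained `model`
#'   (restored to its best epoch), and `epoch_seconds`.
#' @export
train <- function(model, train_set, val_set, cfg = train_config(),
                  checkpoint_path = NULL, history_path = NULL,
                  verbose = FALSE) {
  if (length(train_set) == 0L || length(val_set) == 0L) {
    stop("train: datasets must be nonempty")
  }
  set.seed(cfg$seed)
  if (inherits(model, "unet3d_config")) model <- build_unet3d(model)
  params <- parameters(model)
  opt <- optimizer_state(params, cfg)
  n <- length(train_set)
  hist <- vector("list", cfg$epochs)
  best <- list(dice = -Inf, epoch = 0L, state = NULL)
  epoch_secs <- numeric(cfg$epochs)
  for (e in seq_len(cfg$epochs)) {
    t0 <- proc.time()[3]
    lr <- lr_schedule(e, cfg)
    ord <- sample.int(n)
    losses <- numeric(0)
    b <- 0L
    i <- 1L
    while (i <= n) {
      b <- b + 1L
      take <- ord[i:min(i + cfg$batch_size - 1L, n)]
      i <- i + cfg$batch_size
      zero_grads(params)
      batch_loss <- 0
      for (j in take) {
        pair <- augment(train_set[[j]], cfg)
        loss <- ag_seg_loss(forward(model, as_model_input(pair$image),
                                    training = TRUE),
                            as_model_input(pair$mask), cfg$loss)
        lv <- ag_value(loss)
        if (!is.finite(lv)) {
          stop("train: non-finite loss at epoch ", e, ", batch ", b,
               " (sample ", j, "); aborting")
        }
        batch_loss <- batch_loss + lv
        ag_backward(loss, grad = 1 / length(take))
      }
      losses <- c(losses, batch_loss / length(take))
      opt <- optimizer_step(opt, params, lr)
    }
    vm <- evaluate(model, val_set)
    if (vm$macro[["dsc"]] > best$dice) {
      best$dice <- vm$macro[["dsc"]]
      best$epoch <- e
      best$state <- module_state(model)
    }
    epoch_secs[e] <- proc.time()[3] - t0
    hist[[e]] <- data.frame(epoch = e, train_loss = mean(losses),
                            val_DSC = vm$macro[["dsc"]],
                            val_SEN = vm$macro[["sen"]],
                            val_PPV = vm$macro[["ppv"]], lr = lr)
    if (verbose) {
      message(sprintf("epoch %d/%d loss %.4f val DSC %.4f lr %.5f",
                      e, cfg$epochs, mean(losses), vm$macro[["dsc"]], lr))
    }
  }
  history <- do.call(rbind, hist)
  load_module_state(model, best$state)
  if (!is.null(history_path)) {
    utils::write.csv(history, history_path, row.names = FALSE)
  }
  if (!is.null(checkpoint_path)) {
    save_checkpoint(model, checkpoint_path,
                    meta = list(best_epoch = best$epoch,
                                best_val_dice = best$dice, seed = cfg$seed))
  }
  list(history = history, best_epoch = best$epoch, best_val_dice = best$dice,
       model = model, epoch_seconds = epoch_secs)
}

#' Evaluate a model on a dataset
#'
#' Per-volume Dice, sensitivity and PPV at the given probability threshold,
#' macro-averaged.
#'
#' @param model a trained `unet3d`.
#' @param dataset nonempty list of pairs with `image` and `mask`.
#' @param threshold probability threshold for hard masks.
#' @return list with `per_volume` (data.frame) and `macro` (named means).
#' @export
evaluate <- function(model, dataset, threshold = 0.5) {
  if (length(dataset) == 0L) stop("evaluate: dataset is empty")
  rows <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    p <- predict_prob(model, dataset[[i]]$image)
    m <- segmentation_metrics(p >= threshold, dataset[[i]]$mask)
    rows[[i]] <- data.frame(volume = i, dsc = m[["dsc"]], sen = m[["sen"]],
                            ppv = m[["ppv"]])
  }
  tab <- do.call(rbind, rows)
  list(per_volume = tab,
       macro = c(dsc = mean(tab$dsc), sen = mean(tab$sen),
                 ppv = mean(tab$ppv)))
}

# voxel-micro F1 over a dataset (identical in form to Dice on hard masks,
# but pooled over voxels instead of averaged per volume)
micro_f1 <- function(model, dataset, threshold = 0.5) {
  tp <- 0; fp <- 0; fn <- 0
  for (d in dataset) {
    cc <- confusion_counts(predict_prob(model, d$image), d$mask, threshold)
    tp <- tp + cc[["TP"]]; fp <- fp + cc[["FP"]]; fn <- fn + cc[["FN"]]
  }
  if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
}

#' Paired two-sided t-test
#'
#' @param scores_a,scores_b equal-length score vectors, `n >= 2`.
#' @return list with `t`, `p_two_sided`, `mean_diff`, `ci95`. Zero variance
#'   of the differences returns `t = 0` when the mean difference is 0 and
#'   the `t = Inf` convention (sign of the mean difference) with a warning
#'   otherwise.
#' @export
paired_t_test <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2)
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p_two_sided = 1, mean_diff = 0, ci95 = c(0, 0)))
    }
    warning("paired_t_test: zero variance of differences; t = Inf convention")
    return(list(t = sign(mean(d)) * Inf, p_two_sided = 0,
                mean_diff = mean(d), ci95 = c(mean(d), mean(d))))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(tt$statistic), p_two_sided = tt$p.value,
       mean_diff = unname(tt$estimate), ci95 = as.numeric(tt$conf.int))
}

#' Run the ablation ladder
#'
#' Trains every requested variant of [ablation_variants()] under one shared
#' seed and data split and tabulates the best validation metrics.
#'
#' @param variants character vector of variant names.
#' @param train_set,val_set patch pair lists.
#' @param cfg a [train_config()].
#' @param base_channels,... forwarded to [unet3d_config()].
#' @return data.frame with one row per variant (`variant`, `params`,
#'   `best_epoch`, `best_val_dice`, `val_sen`, `val_ppv`).
#' @export
ablation_run <- function(variants, train_set, val_set, cfg = train_config(),
                         base_channels = 64L, ...) {
  rows <- vector("list", length(variants))
  for (i in seq_along(variants)) {
    mc <- unet3d_config(variant = variants[i], base_channels = base_channels,
                        ...)
    res <- train(mc, train_set, val_set, cfg)
    h <- res$history[res$history$epoch == res$best_epoch, ]
    rows[[i]] <- data.frame(variant = variants[i],
                            params = n_parameters(res$model),
                            best_epoch = res$best_epoch,
                            best_val_dice = res$best_val_dice,
                            val_sen = h$val_SEN, val_ppv = h$val_PPV)
  }
  do.call(rbind, rows)
}

#' Compare optimizers under one seed
#'
#' Trains the same model configuration with each optimizer and reports the
#' best validation Dice, the voxel-micro F1 of the best checkpoint, and the
#' mean epoch time. Timing is informational only (hardware-dependent) and is
#' never asserted on.
#'
#' @param model_cfg a [unet3d_config()].
#' @param train_set,val_set patch pair lists.
#' @param cfg a [train_config()]; its `optimizer` field is overridden.
#' @param optimizers optimizers to compare.
#' @return data.frame (`optimizer`, `dice`, `f1`, `mean_epoch_seconds`).
#' @export
compare_optimizers <- function(model_cfg, train_set, val_set,
                               cfg = train_config(),
                               optimizers = c("adam", "adamw", "radam")) {
  rows <- vector("list", length(optimizers))
  for (i in seq_along(optimizers)) {
    ci <- cfg
    ci$optimizer <- optimizers[i]
    res <- train(model_cfg, train_set, val_set, ci)
    rows[[i]] <- data.frame(optimizer = optimizers[i],
                            dice = res$best_val_dice,
                            f1 = micro_f1(res$model, val_set),
                            mean_epoch_seconds = mean(res$epoch_seconds))
  }
  do.call(rbind, rows)
}

#' Build a PSO fitness callback from a training setup
#'
#' Maps a swarm position `(wd, w_bce, w_dice)` to the negative best
#' validation Dice of a training run with those hyperparameters (the IoU
#' weight is derived via the swarm's rule).
#'
#' @param model_cfg a [unet3d_config()].
#' @param train_set,val_set patch pair lists.
#' @param cfg a [train_config()] providing everything but the tuned fields.
#' @param swarm_cfg a [swarm_config()] (for the IoU-weight rule).
#' @return function(position) -> negative validation Dice.
#' @export
make_dice_fitness <- function(model_cfg, train_set, val_set,
                              cfg = train_config(),
                              swarm_cfg = swarm_config()) {
  function(position) {
    ci <- cfg
    ci$weight_decay <- position[["wd"]]
    w_iou <- derived_iou_weight(position, swarm_cfg)
    s <- position[["w_bce"]] + position[["w_dice"]] + w_iou
    ci$loss <- loss_weights(position[["w_bce"]] / s,
                            position[["w_dice"]] / s, w_iou / s,
                            alpha = cfg$loss$alpha,
                            epsilon = cfg$loss$epsilon)
    -train(model_cfg, train_set, val_set, ci)$best_val_dice
  }
}
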