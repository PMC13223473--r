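# Particle swarm search over (weight_decay, w_bce, w_dice), minimizing a
# fitness callback (negative validation Dice in the training pipeline). The
# IoU weight is derived, keeping the loss weights on the simplex.

#' Swarm configuration
#'
#' @param n_pop number of particles (>= 2).
#' @param max_iter number of iterations (>= 1).
#' @param inertia inertia weight `w`.
#' @param c1,c2 cognitive and social acceleration coefficients.
#' @param bounds named list of `c(lower, upper)` for `wd` (weight decay,
#'   sampled log-uniformly), `w_bce` and `w_dice`.
#' @param seed RNG seed; the full trajectory is reproducible given the seed
#'   and a deterministic objective.
#' @param iou_rule how the derived IoU weight is computed:
#'   `"one_minus_bce_dice"` (default) sets `w_iou = max(0, 1 - w_bce -
#'   w_dice)`, which keeps the full triple on the simplex;
#'   `"one_minus_bce"` sets `w_iou = max(0, 1 - w_bce)`.
#' @return a `swarm_config` list.
#' @export
swarm_config <- function(n_pop = 10L, max_iter = 20L, inertia = 0.7,
                         c1 = 1.5, c2 = 1.5,
                         bounds = list(wd = c(1e-5, 1e-2),
                                       w_bce = c(0.1, 0.6),
                                       w_dice = c(0.2, 0.7)),
                         seed = 0L,
                         iou_rule = c("one_minus_bce_dice",
                                      "one_minus_bce")) {
  iou_rule <- match.arg(iou_rule)
  if (n_pop < 2L) stop("swarm_config: n_pop must be >= 2")
  if (max_iter < 1L) stop("swarm_config: max_iter must be >= 1")
  stopifnot(setequal(names(bounds), c("wd", "w_bce", "w_dice")))
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2L || !(b[1] < b[2])) {
      stop("swarm_config: bounds$", nm, " must be a nonempty interval")
    }
  }
  structure(list(n_pop = as.integer(n_pop), max_iter = as.integer(max_iter),
                 inertia = inertia, c1 = c1, c2 = c2,
                 bounds = bounds[c("wd", "w_bce", "w_dice")],
                 seed = as.integer(seed), iou_rule = iou_rule),
            class = "swarm_config")
}

pso_clip_project <- function(x, cfg) {
  bl <- vapply(cfg$bounds, `[`, numeric(1), 1L)
  bu <- vapply(cfg$bounds, `[`, numeric(1), 2L)
  x <- pmin(pmax(x, bl), bu)
  s <- x[2] + x[3]
  if (s > 1) {           # re-project the weight pair onto the simplex face
    x[2:3] <- x[2:3] / s
    x[2:3] <- pmin(pmax(x[2:3], bl[2:3]), bu[2:3])
  }
  x
}

#' Initialize a particle swarm
#'
#' Positions are drawn uniformly within bounds (log-uniformly for the weight
#' decay); draws whose loss-weight pair leaves the simplex are re-projected
#' onto its boundary. Velocities are uniform within +/- 10 percent of each
#' bound's width. Consumes the global RNG; callers seed it (as [run_pso()]
#' does from `cfg$seed`).
#'
#' @param cfg a [swarm_config()].
#' @return list of particles, each with `position`, `velocity`,
#'   `best_position`, `best_fitness`.
#' @export
init_swarm <- function(cfg) {
  b <- cfg$bounds
  lapply(seq_len(cfg$n_pop), function(i) {
    wd <- exp(stats::runif(1, log(b$wd[1]), log(b$wd[2])))
    wb <- stats::runif(1, b$w_bce[1], b$w_bce[2])
    wdc <- stats::runif(1, b$w_dice[1], b$w_dice[2])
    pos <- pso_clip_project(c(wd = wd, w_bce = wb, w_dice = wdc), cfg)
    widths <- vapply(b, diff, numeric(1))
    vel <- stats::runif(3, -0.1, 0.1) * widths
    list(position = pos, velocity = vel,
         best_position = pos, best_fitness = Inf)
  })
}

derived_iou_weight <- function(pos, cfg) {
  if (cfg$iou_rule == "one_minus_bce_dice") {
    max(0, 1 - pos[["w_bce"]] - pos[["w_dice"]])
  } else {
    max(0, 1 - pos[["w_bce"]])
  }
}

#' One particle swarm iteration
#'
#' Evaluates the fitness of every particle at its current position (failures
#' raise a warning and skip the particle), updates personal and global
#' bests, then applies the velocity and position updates
#' `v <- w v + c1 r1 (p_best - x) + c2 r2 (g_best - x)`,
#' `x <- clip(x + v)` with simplex re-projection.
#'
#' @param particles list from [init_swarm()].
#' @param g_best list with `position` and `fitness` (use `fitness = Inf`
#'   before the first iteration).
#' @param cfg a [swarm_config()].
#' @param objective function mapping a named position vector to a scalar
#'   fitness (minimized).
#' @param cache optional environment used to memoize fitness by position
#'   rounded to 6 decimals.
#' @return list with updated `particles`, `g_best`, and an `evals`
#'   data.frame (`particle`, `wd`, `w_bce`, `w_dice`, `fitness`).
#' @export
pso_step <- function(particles, g_best, cfg, objective, cache = NULL) {
  evals <- vector("list", length(particles))
  for (i in seq_along(particles)) {
    p <- particles[[i]]
    f <- pso_evaluate(objective, p$position, cache)
    evals[[i]] <- data.frame(particle = i, wd = p$position[[1]],
                             w_bce = p$position[[2]],
                             w_dice = p$position[[3]],
                             fitness = if (is.null(f)) NA_real_ else f)
    if (is.null(f)) next
    if (f < p$best_fitness) {
      p$best_fitness <- f
      p$best_position <- p$position
    }
    if (f < g_best$fitness) {
      g_best$fitness <- f
      g_best$position <- p$position
    }
    particles[[i]] <- p
  }
  for (i in seq_along(particles)) {
    p <- particles[[i]]
    r1 <- stats::runif(3); r2 <- stats::runif(3)
    gb <- if (is.finite(g_best$fitness)) g_best$position else p$best_position
    p$velocity <- cfg$inertia * p$velocity +
      cfg$c1 * r1 * (p$best_position - p$position) +
      cfg$c2 * r2 * (gb - p$position)
    p$position <- pso_clip_project(p$position + p$velocity, cfg)
    particles[[i]] <- p
  }
  list(particles = particles, g_best = g_best, evals = do.call(rbind, evals))
}

pso_evaluate <- function(objective, position, cache) {
  key <- paste(round(position, 6), collapse = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  f <- tryCatch(objective(position), error = function(e) {
    warning("pso: objective failed at (", key, "): ", conditionMessage(e))
    NULL
  })
  if (!is.null(f) && !is.null(cache)) cache[[key]] <- f
  f
}

#' Run particle swarm optimization
#'
#' @param objective function mapping a named position vector
#'   `(wd, w_bce, w_dice)` to a scalar fitness, minimized (use the negative
#'   validation Dice to maximize Dice).
#' @param cfg a [swarm_config()].
#' @return list with the best position (`wd_opt`, `w_bce_opt`, `w_dice_opt`,
#'   the derived `w_iou_opt`), `best_fitness`, `history` (per-iteration best
#'   fitness, monotone non-increasing) and the full evaluation `trace`.
#' @export
run_pso <- function(objective, cfg = swarm_config()) {
  set.seed(cfg$seed)
  particles <- init_swarm(cfg)
  g_best <- list(position = particles[[1]]$position, fitness = Inf)
  cache <- new.env(parent = emptyenv())
  hist <- numeric(cfg$max_iter)
  trace <- vector("list", cfg$max_iter)
  for (it in seq_len(cfg$max_iter)) {
    st <- pso_step(particles, g_best, cfg, objective, cache)
    particles <- st$particles
    g_best <- st$g_best
    hist[it] <- g_best$fitness
    tr <- st$evals
    tr$iter <- it
    tr$g_best <- g_best$fitness
    trace[[it]] <- tr
  }
  pos <- g_best$position
  list(wd_opt = pos[["wd"]], w_bce_opt = pos[["w_bce"]],
       w_dice_opt = pos[["w_dice"]],
       w_iou_opt = derived_iou_weight(pos, cfg),
       best_fitness = g_best$fitness,
       history = data.frame(iter = seq_len(cfg$max_iter),
                            best_fitness = hist),
       trace = do.call(rbind, trace)[, c("iter", "particle", "wd", "w_bce",
                                         "w_dice", "fitness", "g_best")])
}
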