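# Seeded synthetic phantom generator emitting CT-like patch/mask pairs in
# the processed-patch layout, so the full pipeline runs without any dataset
# download. Patches mimic post-preprocessing chest CT: dim parenchyma
# texture, bright tubular vessels, and (usually) one lobulated nodule.

#' Phantom generator configuration
#'
#' Defaults are the study conditions of the synthetic data source and are
#' chosen to mirror the population structure of screening CT nodules: a
#' truncated log-normal diameter law (median 6 mm, log-sd 0.45, support
#' [3, 30] mm) puts at least 80 percent of diameters at or below 10 mm, and
#' the patch geometry keeps the positive-voxel fraction of an emitted set
#' below 1 percent.
#'
#' @param n_patches number of patch/mask pairs.
#' @param patch_shape integer `(z, y, x)` patch shape.
#' @param spacing voxel spacing in mm, `(z, y, x)` order.
#' @param diameter_median,diameter_sdlog log-normal diameter parameters (mm).
#' @param diameter_range truncation interval in mm.
#' @param fraction_empty fraction of patches rendered without a nodule.
#' @param contrast nodule-over-background intensity gap (post-normalization
#'   units).
#' @param noise_sigma additive Gaussian noise level.
#' @param vessel_density expected number of vessel segments per patch.
#' @param lobulation_amplitude relative radius perturbation bound in
#'   `[0, 0.5]` of the degree-2 spherical-harmonic lobulation.
#' @param seed RNG seed; `(cfg, seed)` fully determines every emitted byte.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(n_patches = 100L,
                           patch_shape = c(16L, 96L, 96L),
                           spacing = c(2.0, 0.7, 0.7),
                           diameter_median = 6,
                           diameter_sdlog = 0.45,
                           diameter_range = c(3, 30),
                           fraction_empty = 0.1,
                           contrast = 0.4,
                           noise_sigma = 0.05,
                           vessel_density = 2,
                           lobulation_amplitude = 0.2,
                           seed = 0L) {
  stopifnot(n_patches >= 1, length(patch_shape) == 3, length(spacing) == 3,
            all(spacing > 0), diameter_median > 0, diameter_sdlog > 0,
            diameter_range[1] > 0, diameter_range[1] < diameter_range[2],
            fraction_empty >= 0, fraction_empty <= 1,
            lobulation_amplitude >= 0, lobulation_amplitude <= 0.5,
            noise_sigma >= 0, vessel_density >= 0)
  structure(list(n_patches = as.integer(n_patches),
                 patch_shape = as.integer(patch_shape),
                 spacing = as.numeric(spacing),
                 diameter_median = diameter_median,
                 diameter_sdlog = diameter_sdlog,
                 diameter_range = as.numeric(diameter_range),
                 fraction_empty = fraction_empty,
                 contrast = contrast,
                 noise_sigma = noise_sigma,
                 vessel_density = vessel_density,
                 lobulation_amplitude = lobulation_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Draw one nodule specification
#'
#' The diameter is log-normal (median `diameter_median`, log-sd
#' `diameter_sdlog`) truncated to `diameter_range` by rejection; the center
#' is uniform within the patch interior, leaving a margin of the nodule's
#' maximal voxel radius per axis where the patch allows it. Consumes the
#' global RNG.
#'
#' @param cfg a [phantom_config()].
#' @return a `nodule_spec` list with `center` (voxel, `(z,y,x)`, 0-based,
#'   fractional), `diameter_mm`, `lobulation_amplitude`, `contrast`,
#'   `spacing`, and the 5 lobulation coefficients.
#' @export
sample_nodule_spec <- function(cfg) {
  r <- cfg$diameter_range
  d <- Inf
  while (d < r[1] || d > r[2]) {
    d <- stats::rlnorm(1, meanlog = log(cfg$diameter_median),
                       sdlog = cfg$diameter_sdlog)
  }
  rmax_vox <- (d / 2) * (1 + cfg$lobulation_amplitude) / cfg$spacing
  lo <- pmin(rmax_vox, (cfg$patch_shape - 1) / 2)
  hi <- pmax(cfg$patch_shape - 1 - rmax_vox, (cfg$patch_shape - 1) / 2)
  center <- stats::runif(3, lo, hi)
  coefs <- stats::runif(5, -1, 1)
  structure(list(center = center, diameter_mm = d,
                 lobulation_amplitude = cfg$lobulation_amplitude,
                 contrast = cfg$contrast, spacing = cfg$spacing,
                 lobulation_coefs = coefs),
            class = "nodule_spec")
}

# bounded degree-2 spherical-harmonic radius perturbation for unit
# directions (rows dz, dy, dx in mm, already normalized)
lobulation_perturbation <- function(uz, uy, ux, coefs, amplitude) {
  if (amplitude == 0) return(0)
  basis <- cbind((3 * uz^2 - 1) / 2, ux^2 - uy^2, ux * uy, ux * uz, uy * uz)
  amplitude * as.vector(basis %*% coefs) / sum(abs(coefs))
}

# exact voxelization: voxel center inside the perturbed sphere surface
nodule_mask <- function(spec, patch_shape) {
  sp <- spec$spacing
  dz <- (seq_len(patch_shape[1]) - 1 - spec$center[1]) * sp[1]
  dy <- (seq_len(patch_shape[2]) - 1 - spec$center[2]) * sp[2]
  dx <- (seq_len(patch_shape[3]) - 1 - spec$center[3]) * sp[3]
  Z <- array(dz, patch_shape)
  Y <- array(rep(dy, each = patch_shape[1]), patch_shape)
  X <- array(rep(dx, each = patch_shape[1] * patch_shape[2]), patch_shape)
  rho <- sqrt(Z^2 + Y^2 + X^2)
  r0 <- spec$diameter_mm / 2
  safe <- pmax(rho, 1e-12)
  pert <- lobulation_perturbation(Z / safe, Y / safe, X / safe,
                                  spec$lobulation_coefs,
                                  spec$lobulation_amplitude)
  mask <- rho <= r0 * (1 + pert)
  storage.mode(mask) <- "double"
  dim(mask) <- patch_shape
  mask
}

#' Analytic volume of a (possibly lobulated) nodule
#'
#' Integrates `r(u)^3 / 3` over the sphere of directions with a Fibonacci
#' quadrature grid; for zero lobulation this is exactly `4/3 pi r^3`.
#'
#' @param spec a nodule specification from [sample_nodule_spec()].
#' @param n number of quadrature directions.
#' @return volume in cubic mm.
#' @export
nodule_analytic_volume <- function(spec, n = 20000L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  uz <- cos(phi); uy <- sin(phi) * sin(theta); ux <- sin(phi) * cos(theta)
  r0 <- spec$diameter_mm / 2
  pert <- lobulation_perturbation(uz, uy, ux, spec$lobulation_coefs,
                                  spec$lobulation_amplitude)
  mean((r0 * (1 + pert))^3) * 4 * pi / 3
}

# coarse-noise parenchyma texture upscaled trilinearly to the patch grid
parenchyma_texture <- function(patch_shape, base = 0.15, amp = 0.05) {
  coarse <- pmax(patch_shape %/% 4L, 2L)
  g <- array(stats::rnorm(prod(coarse)), coarse)
  tx <- resample_trilinear(g, dim_out = patch_shape)
  base + amp * tx
}

# bright tube segments crossing the patch
add_vessels <- function(img, spacing, density) {
  n <- stats::rpois(1, density)
  if (n == 0) return(img)
  d <- dim(img)
  dz <- (seq_len(d[1]) - 1) * spacing[1]
  dy <- (seq_len(d[2]) - 1) * spacing[2]
  dx <- (seq_len(d[3]) - 1) * spacing[3]
  Z <- array(dz, d)
  Y <- array(rep(dy, each = d[1]), d)
  X <- array(rep(dx, each = d[1] * d[2]), d)
  ext <- (d - 1) * spacing
  for (i in seq_len(n)) {
    p0 <- stats::runif(3, 0, ext)
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2))
    radius <- stats::runif(1, 0.5, 1.5)
    intensity <- stats::runif(1, 0.25, 0.45)
    wz <- Z - p0[1]; wy <- Y - p0[2]; wx <- X - p0[3]
    t <- wz * v[1] + wy * v[2] + wx * v[3]
    dist2 <- (wz - t * v[1])^2 + (wy - t * v[2])^2 + (wx - t * v[3])^2
    img <- img + intensity * (dist2 <= radius^2)
  }
  img
}

#' Render one phantom patch
#'
#' Background is parenchyma texture plus random vessel cylinders plus
#' Gaussian noise; when `spec` is non-NULL a lobulated nodule of intensity
#' `background + contrast` is added and its exact voxelization becomes the
#' mask. If the nodule's maximal extent overflows the patch at its sampled
#' center it is re-centered onto the patch center with a warning. Consumes
#' the global RNG.
#'
#' @param spec a `nodule_spec` or NULL for an empty patch.
#' @param cfg a [phantom_config()].
#' @param series_id identifier used in the annotation row.
#' @return list with `image`, `mask` (both `(z, y, x)` arrays) and
#'   `annotation`, a one-row data.frame in the annotations-CSV dialect
#'   (`seriesuid`, `coordX`, `coordY`, `coordZ`, `diameter_mm`; world
#'   coordinates in mm with the origin at voxel `(0, 0, 0)`), with zero rows
#'   for an empty patch.
#' @export
render_phantom <- function(spec, cfg, series_id = "phantom") {
  ps <- cfg$patch_shape
  img <- parenchyma_texture(ps)
  img <- add_vessels(img, cfg$spacing, cfg$vessel_density)
  if (!is.null(spec)) {
    rmax_vox <- (spec$diameter_mm / 2) * (1 + spec$lobulation_amplitude) /
      cfg$spacing
    if (any(spec$center < rmax_vox - 0.5 & spec$center < (ps - 1) / 2 - 1e-9) ||
        any(spec$center > ps - 1 - rmax_vox + 0.5 &
            spec$center > (ps - 1) / 2 + 1e-9)) {
      warning("render_phantom: nodule overflows the patch; re-centering")
      spec$center <- (ps - 1) / 2
    }
    mask <- nodule_mask(spec, ps)
    img <- img + spec$contrast * mask
    ann <- data.frame(seriesuid = series_id,
                      coordX = spec$center[3] * cfg$spacing[3],
                      coordY = spec$center[2] * cfg$spacing[2],
                      coordZ = spec$center[1] * cfg$spacing[1],
                      diameter_mm = spec$diameter_mm)
  } else {
    mask <- array(0, ps)
    ann <- data.frame(seriesuid = character(), coordX = numeric(),
                      coordY = numeric(), coordZ = numeric(),
                      diameter_mm = numeric())
  }
  img <- img + cfg$noise_sigma * array(stats::rnorm(prod(ps)), ps)
  list(image = img, mask = mask, annotation = ann)
}

#' Generate a phantom patch set in memory
#'
#' Seeds the global RNG from `cfg$seed` and emits `n_patches` pairs; a
#' `fraction_empty` share of patches (decided per patch) carries no nodule.
#'
#' @param cfg a [phantom_config()].
#' @return list with `pairs` (list of `image`/`mask`/`annotation`),
#'   `annotations` (combined data.frame) and `positive_fraction`.
#' @export
generate_patches <- function(cfg) {
  set.seed(cfg$seed)
  pairs <- vector("list", cfg$n_patches)
  anns <- vector("list", cfg$n_patches)
  pos <- 0; tot <- 0
  for (i in seq_len(cfg$n_patches)) {
    sid <- sprintf("phantom-%04d", i)
    empty <- stats::runif(1) < cfg$fraction_empty
    spec <- if (empty) NULL else sample_nodule_spec(cfg)
    p <- render_phantom(spec, cfg, series_id = sid)
    p$series_id <- sid
    pairs[[i]] <- p
    anns[[i]] <- p$annotation
    pos <- pos + sum(p$mask); tot <- tot + length(p$mask)
  }
  list(pairs = pairs, annotations = do.call(rbind, anns),
       positive_fraction = pos / tot)
}

#' Generate a phantom dataset on disk
#'
#' Writes each pair as a compressed array archive plus a manifest CSV
#' (`series_id`, `subset`, `patch_path`, `mask_path`; synthetic subset tags
#' cycle 0-9 so [split_subsets()] applies), the annotations CSV, and a stats
#' file recording the positive-voxel fraction. Fully deterministic:
#' identical `(cfg, seed)` produce byte-identical manifests.
#'
#' @param cfg a [phantom_config()].
#' @param outdir writable output directory (created if needed).
#' @return the manifest data.frame, invisibly, with the dataset paths in
#'   attributes.
#' @export
generate_dataset <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gp <- generate_patches(cfg)
  rows <- vector("list", length(gp$pairs))
  for (i in seq_along(gp$pairs)) {
    p <- gp$pairs[[i]]
    pp <- file.path(outdir, sprintf("%s_img.rds", p$series_id))
    mp <- file.path(outdir, sprintf("%s_mask.rds", p$series_id))
    saveRDS(p$image, pp)
    saveRDS(p$mask, mp)
    rows[[i]] <- data.frame(series_id = p$series_id,
                            subset = (i - 1L) %% 10L,
                            patch_path = basename(pp),
                            mask_path = basename(mp))
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(gp$annotations, file.path(outdir, "annotations.csv"),
                   row.names = FALSE)
  writeLines(sprintf("positive_voxel_fraction,%.10f", gp$positive_fraction),
             file.path(outdir, "stats.csv"))
  attr(manifest, "positive_fraction") <- gp$positive_fraction
  attr(manifest, "outdir") <- outdir
  invisible(manifest)
}
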