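# Phantom generator: distributional contract, mask fidelity, determinism.

test_that("sampled diameters obey the truncated log-normal contract", {
  set.seed(0)
  cfg <- phantom_config()
  d <- replicate(1000, sample_nodule_spec(cfg)$diameter_mm)
  expect_true(all(d >= 3 & d <= 30))
  expect_gte(mean(d <= 10), 0.80)
})

test_that("fixed seed gives an identical spec sequence", {
  cfg <- phantom_config()
  set.seed(5); s1 <- replicate(20, sample_nodule_spec(cfg), simplify = FALSE)
  set.seed(5); s2 <- replicate(20, sample_nodule_spec(cfg), simplify = FALSE)
  expect_identical(s1, s2)
})

test_that("sphere voxelization matches the analytic volume within 10%", {
  spec <- structure(list(center = c(8, 48, 48), diameter_mm = 10,
                         lobulation_amplitude = 0, contrast = 0.4,
                         spacing = c(1, 1, 1),
                         lobulation_coefs = rep(0, 5)),
                    class = "nodule_spec")
  m <- nodule_mask(spec, c(17L, 97L, 97L))
  v_analytic <- 4 * pi * 5^3 / 3          # 523.6 voxels at 1 mm isotropic
  expect_lt(abs(sum(m) - v_analytic) / v_analytic, 0.10)
  expect_equal(nodule_analytic_volume(spec), v_analytic, tolerance = 1e-6)
})

test_that("lobulated masks stay within 10% of the analytic volume (>= 6 mm)", {
  set.seed(43)
  cfg <- phantom_config(lobulation_amplitude = 0.2)
  for (i in 1:5) {
    spec <- sample_nodule_spec(cfg)
    if (spec$diameter_mm < 6) next
    m <- nodule_mask(spec, cfg$patch_shape)
    vox_volume <- sum(m) * prod(cfg$spacing)
    expect_lt(abs(vox_volume - nodule_analytic_volume(spec)) /
                nodule_analytic_volume(spec), 0.10)
  }
})

test_that("rendered phantoms have binary masks inside patch bounds", {
  set.seed(44)
  cfg <- phantom_config(n_patches = 3)
  spec <- sample_nodule_spec(cfg)
  p <- render_phantom(spec, cfg)
  expect_equal(dim(p$mask), cfg$patch_shape)
  expect_true(all(p$mask %in% c(0, 1)))
  expect_equal(nrow(p$annotation), 1L)
  expect_equal(p$annotation$diameter_mm, spec$diameter_mm)
})

test_that("zero contrast leaves the mask intact but removes the signal", {
  set.seed(45)
  cfg <- phantom_config(contrast = 0)
  spec <- sample_nodule_spec(cfg)
  p <- render_phantom(spec, cfg)
  expect_gt(sum(p$mask), 0)
  # nodule region intensity indistinguishable from background level
  inside <- mean(p$image[p$mask == 1])
  outside <- mean(p$image[p$mask == 0])
  expect_lt(abs(inside - outside), 0.1)
})

test_that("an overflowing nodule is re-centered with a warning", {
  cfg <- phantom_config(patch_shape = c(8L, 24L, 24L))
  spec <- structure(list(center = c(0, 0, 0), diameter_mm = 28,
                         lobulation_amplitude = 0, contrast = 0.4,
                         spacing = cfg$spacing, lobulation_coefs = rep(0, 5)),
                    class = "nodule_spec")
  set.seed(46)
  expect_warning(p <- render_phantom(spec, cfg), "re-centering")
  expect_true(all(p$mask %in% c(0, 1)))
})

test_that("generated sets satisfy the statistical contract", {
  gp <- generate_patches(phantom_config(n_patches = 40, seed = 9))
  expect_lt(gp$positive_fraction, 0.01)
  expect_equal(length(gp$pairs), 40L)
})

test_that("fraction_empty = 1 gives only empty masks", {
  gp <- generate_patches(phantom_config(n_patches = 5, fraction_empty = 1,
                                        seed = 1))
  expect_true(all(vapply(gp$pairs, function(p) sum(p$mask), 0) == 0))
  expect_equal(nrow(gp$annotations), 0L)
})

test_that("same seed produces byte-identical datasets on disk", {
  cfg <- phantom_config(n_patches = 4, patch_shape = c(8L, 16L, 16L),
                        seed = 3)
  d1 <- tempfile(); d2 <- tempfile()
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     info = f)
  }
  m <- utils::read.csv(file.path(d1, "manifest.csv"))
  expect_equal(names(m), c("series_id", "subset", "patch_path", "mask_path"))
  expect_equal(sort(unique(m$subset)), 0:3)
  pairs <- load_dataset(d1)
  expect_equal(length(pairs), 4L)
  expect_equal(dim(pairs[[1]]$image), c(8, 16, 16))
})
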