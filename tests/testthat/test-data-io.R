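# Volume I/O, coordinate mapping, preprocessing, patch extraction, contour
# rasterization, and subset splitting.

test_that("MetaImage write/read round-trips voxels, origin and spacing", {
  set.seed(51)
  v <- ct_volume(array(rnorm(8 * 8 * 8), c(8, 8, 8)),
                 origin = c(-12.5, 3, 40), spacing = c(2.5, 0.7, 0.7),
                 series_id = "toy")
  path <- file.path(tempdir(), "toy.mhd")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_identical(v2$voxels, v$voxels)
  expect_equal(v2$origin, v$origin)
  expect_equal(v2$spacing, c(2.5, 0.7, 0.7))
})

test_that("integer element types and big-endian buffers read correctly", {
  v <- ct_volume(array(round(rnorm(4 * 3 * 2, 0, 100)), c(4, 3, 2)))
  path <- file.path(tempdir(), "short.mhd")
  write_volume(v, path, element_type = "MET_SHORT")
  expect_identical(read_volume(path)$voxels, v$voxels)
})

test_that("a truncated raw file errors naming expected vs actual bytes", {
  v <- ct_volume(array(1, c(4, 4, 4)))
  path <- file.path(tempdir(), "trunc.mhd")
  write_volume(v, path)
  raw_path <- file.path(tempdir(), "trunc.raw")
  writeBin(readBin(raw_path, "raw", 100), raw_path)  # keep 100 of 512 bytes
  expect_error(read_volume(path), "expected 512 bytes.*found 100")
})

test_that("world/voxel mapping matches hand arithmetic and round-trips", {
  v <- ct_volume(array(0, c(10, 10, 10)), origin = c(0, 0, 0),
                 spacing = c(1, 1, 1))
  expect_equal(world_to_voxel(c(0, 0, 0), v), c(0L, 0L, 0L))
  expect_equal(world_to_voxel(c(5.4, 2.0, 3.0), v), c(3L, 2L, 5L))
  # inverse recovers the coordinate within half a voxel per axis
  v2 <- ct_volume(array(0, c(20, 30, 30)), origin = c(-10, 4, 2),
                  spacing = c(0.7, 0.7, 2.0))
  set.seed(52)
  for (i in 1:20) {
    coord <- c(runif(1, -10, 9), runif(1, 4, 23), runif(1, 2, 39))
    back <- voxel_to_world(world_to_voxel(coord, v2), v2)
    expect_true(all(abs(back - coord) <= v2$spacing / 2 + 1e-9))
  }
  expect_error(world_to_voxel(c(500, 0, 0), v), "out of bounds")
})

test_that("preprocessing masks, normalizes, demeans and is idempotent", {
  set.seed(53)
  vol <- ct_volume(array(rnorm(8 * 10 * 10, -400, 300), c(8, 10, 10)),
                   spacing = c(0.7, 0.7, 2.0))
  mask <- array(0, c(8, 10, 10)); mask[2:7, 3:8, 3:8] <- 1
  p1 <- preprocess_volume(vol, mask, resample = FALSE)
  x <- p1$volume$voxels
  expect_true(all(x[mask == 0] == 0))               # background exactly zero
  expect_lt(abs(mean(x[mask == 1])), 1e-12)         # demeaned inside mask
  expect_equal(diff(range(x[mask == 1])), 1)        # unit masked range
  p2 <- preprocess_volume(p1$volume, mask, resample = FALSE)
  expect_lt(max(abs(p2$volume$voxels - x)), 1e-6)   # idempotent
  expect_error(preprocess_volume(vol, array(1, c(2, 2, 2))),
               "does not match")
})

test_that("all-ones mask reduces the pipeline to normalize + demean", {
  set.seed(54)
  vol <- ct_volume(array(runif(4^3, -500, 200), c(4, 4, 4)))
  p <- preprocess_volume(vol, array(1, c(4, 4, 4)), resample = FALSE)
  x <- p$volume$voxels
  expect_equal(diff(range(x)), 1)
  expect_lt(abs(mean(x)), 1e-12)
})

test_that("resampling a constant volume returns a constant volume", {
  arr <- array(3.7, c(5, 6, 6))
  out <- resample_trilinear(arr, c(2, 0.7, 0.7), c(1, 1, 1))
  expect_lt(max(abs(out - 3.7)), 1e-12)
  nn <- resample_trilinear(arr, c(2, 0.7, 0.7), c(1, 1, 1), mode = "nearest")
  expect_true(all(nn == 3.7))
  # identity when spacings already match
  expect_equal(resample_trilinear(arr, c(1, 1, 1), c(1, 1, 1)), arr)
})

test_that("patch extraction crops, pads and preserves sphere voxel counts", {
  dims <- c(32, 120, 120)
  vol <- ct_volume(array(0, dims), spacing = c(1, 1, 1))
  mask <- array(0, dims)
  ctr <- c(16, 60, 60)  # 0-based voxel center
  for (z in 1:dims[1]) for (y in 1:dims[2]) for (x in 1:dims[3]) {
    if ((z - 1 - ctr[1])^2 + (y - 1 - ctr[2])^2 + (x - 1 - ctr[3])^2 <= 25) {
      mask[z, y, x] <- 1
    }
  }
  ann <- data.frame(coordX = 60, coordY = 60, coordZ = 16, diameter_mm = 10)
  p <- extract_patch(vol, mask, ann)
  expect_equal(dim(p$image), c(16, 96, 96))
  expect_equal(sum(p$mask), sum(mask))   # sphere fully inside the crop
  # mask centroid within a voxel of the patch center
  idx <- which(p$mask == 1, arr.ind = TRUE)
  expect_true(all(abs(colMeans(idx) - c(16, 96, 96) / 2 - 0.5) <= 1))
  # corner annotation still yields an exact-shape zero-padded patch
  ann2 <- data.frame(coordX = 1, coordY = 1, coordZ = 1)
  p2 <- extract_patch(vol, mask, ann2)
  expect_equal(dim(p2$image), c(16, 96, 96))
  ann3 <- data.frame(coordX = 5000, coordY = 0, coordZ = 0)
  expect_error(extract_patch(vol, mask, ann3), "out of bounds")
})

square_xml <- function(z, n_sessions = 1) {
  edges <- paste(sprintf(
    "<edgeMap><xCoord>%d</xCoord><yCoord>%d</yCoord></edgeMap>",
    c(0:9, rep(9, 10), 9:0, rep(0, 10)),
    c(rep(0, 10), 0:9, rep(9, 10), 9:0)), collapse = "")
  one <- sprintf(paste0(
    "<readingSession><unblindedReadNodule><roi>",
    "<imageZposition>%g</imageZposition>%s</roi>",
    "</unblindedReadNodule></readingSession>"), z, edges)
  xml2::read_xml(sprintf("<LidcReadMessage>%s</LidcReadMessage>",
                         paste(rep(one, n_sessions), collapse = "")))
}

test_that("a 10x10 square contour fills exactly 100 voxels on its slice", {
  vol <- ct_volume(array(0, c(3, 20, 20)), spacing = c(1, 1, 1))
  m <- lidc_contours_to_mask(square_xml(1), vol)
  expect_equal(sum(m), 100)
  expect_equal(sum(m[2, , ]), 100)
})

test_that("empty XML gives an all-zero mask; unmatched z warns and skips", {
  vol <- ct_volume(array(0, c(3, 20, 20)), spacing = c(1, 1, 1))
  empty <- xml2::read_xml("<LidcReadMessage></LidcReadMessage>")
  expect_equal(sum(lidc_contours_to_mask(empty, vol)), 0)
  expect_warning(m <- lidc_contours_to_mask(square_xml(7.3), vol),
                 "matches no slice")
  expect_equal(sum(m), 0)
})

test_that("reader consensus keeps voxels present in at least half", {
  vol <- ct_volume(array(0, c(3, 20, 20)), spacing = c(1, 1, 1))
  # two readers marking squares on different slices: every marked voxel has
  # exactly 1 of 2 votes
  session <- function(z) sprintf(paste0(
    "<readingSession><unblindedReadNodule><roi>",
    "<imageZposition>%g</imageZposition>%s</roi>",
    "</unblindedReadNodule></readingSession>"), z,
    paste(sprintf("<edgeMap><xCoord>%d</xCoord><yCoord>%d</yCoord></edgeMap>",
                  c(0:9, rep(9, 10), 9:0, rep(0, 10)),
                  c(rep(0, 10), 0:9, rep(9, 10), 9:0)), collapse = ""))
  doc <- xml2::read_xml(sprintf("<LidcReadMessage>%s%s</LidcReadMessage>",
                                session(0), session(1)))
  # 1 of 2 votes meets the >= 50% default, both slices kept
  expect_equal(sum(lidc_contours_to_mask(doc, vol, consensus = 0.5)), 200)
  # a stricter threshold requires both readers, so nothing survives
  expect_equal(sum(lidc_contours_to_mask(doc, vol, consensus = 0.75)), 0)
  # full agreement survives any threshold
  both <- square_xml(1, n_sessions = 2)
  expect_equal(sum(lidc_contours_to_mask(both, vol, consensus = 1)), 100)
})

test_that("split_subsets partitions 0-7 vs 8-9 and rejects unknown tags", {
  tbl <- data.frame(series_id = sprintf("s%d", 0:9), subset = 0:9)
  sp <- split_subsets(tbl)
  expect_length(sp$train_ids, 8)
  expect_length(sp$val_ids, 2)
  expect_length(intersect(sp$train_ids, sp$val_ids), 0)
  bad <- data.frame(series_id = "x", subset = 11)
  expect_error(split_subsets(bad), "unknown subset")
})
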