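# Volume I/O and the preprocessing pipeline: MetaImage reading/writing,
# world/voxel coordinate mapping, lung masking + normalization + resampling,
# ROI patch extraction, LIDC XML contour rasterization, and subset splits.
#
# Conventions: voxel arrays are (z, y, x) with 0-based voxel indices at the
# API surface; world coordinates are mm in (x, y, z) order, matching the
# annotations-CSV dialect, and are converted at the reader boundary.

#' Construct a CT volume
#'
#' @param voxels 3-D array in `(z, y, x)` order, Hounsfield units.
#' @param origin world position of voxel `(0, 0, 0)`, mm, `(x, y, z)` order.
#' @param spacing voxel spacing, mm, `(x, y, z)` order, all positive.
#' @param series_id identifier string.
#' @return a `ct_volume`.
#' @export
ct_volume <- function(voxels, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                      series_id = "") {
  if (length(dim(voxels)) != 3L || any(dim(voxels) < 1L)) {
    stop("ct_volume: voxels must be a non-degenerate 3-D array")
  }
  if (any(spacing <= 0)) stop("ct_volume: spacing must be positive")
  structure(list(voxels = voxels, origin = as.numeric(origin),
                 spacing = as.numeric(spacing),
                 series_id = as.character(series_id)),
            class = "ct_volume")
}

.meta_types <- list(MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
                    MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
                    MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
                    MET_INT = list(what = "integer", size = 4L, signed = TRUE),
                    MET_FLOAT = list(what = "double", size = 4L, signed = TRUE),
                    MET_DOUBLE = list(what = "double", size = 8L, signed = TRUE))

#' Read a MetaImage volume
#'
#' Parses a `.mhd` text header and its companion raw file. The raw buffer is
#' x-fastest; the array is returned in `(z, y, x)` order with origin and
#' spacing in `(x, y, z)` world order.
#'
#' @param path path to the `.mhd` header.
#' @return a [ct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- trimws(m[3])
  }
  need <- function(key) {
    if (is.null(kv[[key]])) {
      stop("read_volume: malformed header (missing ", key, "): ", path)
    }
    kv[[key]]
  }
  nums <- function(s) as.numeric(strsplit(s, "\\s+")[[1]])
  ndims <- as.integer(need("NDims"))
  if (!identical(ndims, 3L)) {
    stop("read_volume: only NDims = 3 supported, got ", ndims, ": ", path)
  }
  dims <- as.integer(nums(need("DimSize")))           # (x, y, z)
  etype <- need("ElementType")
  tp <- .meta_types[[etype]]
  if (is.null(tp)) stop("read_volume: unsupported ElementType ", etype)
  spacing <- if (!is.null(kv$ElementSpacing)) nums(kv$ElementSpacing)
             else if (!is.null(kv$ElementSize)) nums(kv$ElementSize)
             else c(1, 1, 1)
  origin <- if (!is.null(kv$Offset)) nums(kv$Offset)
            else if (!is.null(kv$Origin)) nums(kv$Origin)
            else if (!is.null(kv$Position)) nums(kv$Position)
            else c(0, 0, 0)
  msb <- isTRUE(toupper(kv$ElementByteOrderMSB %||%
                          kv$BinaryDataByteOrderMSB %||% "FALSE") == "TRUE")
  datafile <- need("ElementDataFile")
  if (identical(datafile, "LOCAL")) {
    stop("read_volume: inline (LOCAL) data not supported: ", path)
  }
  raw_path <- file.path(dirname(path), datafile)
  if (!file.exists(raw_path)) {
    stop("read_volume: companion raw file missing: ", raw_path)
  }
  n <- prod(dims)
  expected <- n * tp$size
  actual <- file.size(raw_path)
  if (actual < expected) {
    stop("read_volume: truncated raw file ", raw_path, ": expected ",
         expected, " bytes (", paste(dims, collapse = "x"), " ", etype,
         "), found ", actual)
  }
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = tp$what, n = n, size = tp$size,
               signed = tp$signed, endian = if (msb) "big" else "little")
  arr <- array(as.double(v), dims)        # (x, y, z)
  arr <- aperm(arr, c(3, 2, 1))           # -> (z, y, x)
  ct_volume(arr, origin = origin, spacing = spacing,
            series_id = sub("\\.mhd$", "", basename(path)))
}

#' Write a MetaImage volume
#'
#' @param vol a [ct_volume()].
#' @param path output `.mhd` path; the raw file is written alongside.
#' @param element_type MetaImage element type (default `MET_DOUBLE`, which
#'   round-trips exactly).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, element_type = "MET_DOUBLE") {
  tp <- .meta_types[[element_type]]
  if (is.null(tp)) stop("write_volume: unsupported ElementType ", element_type)
  d <- dim(vol$voxels)                    # (z, y, x)
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", d[3], d[2], d[1]),
           paste("ElementSpacing =", paste(vol$spacing, collapse = " ")),
           paste("Offset =", paste(vol$origin, collapse = " ")),
           paste("ElementType =", element_type),
           paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  v <- aperm(vol$voxels, c(3, 2, 1))      # -> x-fastest
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  if (tp$what == "integer") {
    writeBin(as.integer(round(v)), con, size = tp$size, endian = "little")
  } else {
    writeBin(as.double(v), con, size = tp$size, endian = "little")
  }
  invisible(path)
}

#' World to voxel coordinate mapping
#'
#' @param coord_mm world coordinate, mm, `(x, y, z)` order.
#' @param vol a [ct_volume()].
#' @return integer voxel index, 0-based, `(z, y, x)` order.
#' @export
world_to_voxel <- function(coord_mm, vol) {
  idx_xyz <- round((coord_mm - vol$origin) / vol$spacing)
  d_xyz <- dim(vol$voxels)[c(3, 2, 1)]
  if (any(idx_xyz < -1) || any(idx_xyz > d_xyz)) {
    stop("world_to_voxel: coordinate out of bounds: world (",
         paste(signif(coord_mm, 6), collapse = ", "), ") mm -> voxel (x,y,z) (",
         paste(idx_xyz, collapse = ", "), "), volume dim (x,y,z) (",
         paste(d_xyz, collapse = ", "), ")")
  }
  idx_xyz <- pmin(pmax(idx_xyz, 0), d_xyz - 1)
  as.integer(rev(idx_xyz))
}

#' Voxel to world coordinate mapping (inverse of [world_to_voxel()])
#'
#' @param idx_zyx 0-based voxel index, `(z, y, x)` order.
#' @param vol a [ct_volume()].
#' @return world coordinate, mm, `(x, y, z)` order.
#' @export
voxel_to_world <- function(idx_zyx, vol) {
  rev(idx_zyx) * vol$spacing + vol$origin
}

#' Preprocessing configuration
#'
#' @param hu_window Hounsfield clipping window before `[0, 1]` scaling.
#' @param target_spacing resampling target, mm, `(z, y, x)` order.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(hu_window = c(-1000, 400),
                              target_spacing = c(2.0, 0.7, 0.7)) {
  stopifnot(hu_window[1] < hu_window[2], all(target_spacing > 0))
  structure(list(hu_window = as.numeric(hu_window),
                 target_spacing = as.numeric(target_spacing)),
            class = "preprocess_config")
}

# per-axis linear / nearest interpolation of a 3-D array at fractional
# 1-based positions along axis `ax`
interp_axis3 <- function(arr, ax, pos, mode) {
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(arr, perm)
  d <- dim(ap)
  m <- matrix(ap, nrow = d[1])
  if (mode == "nearest") {
    out <- m[pmin(pmax(round(pos), 1L), d[1]), , drop = FALSE]
  } else {
    lo <- pmin(pmax(floor(pos), 1), d[1])
    hi <- pmin(lo + 1, d[1])
    fr <- pmin(pmax(pos - lo, 0), 1)
    out <- m[lo, , drop = FALSE] * (1 - fr) + m[hi, , drop = FALSE] * fr
  }
  dim(out) <- c(length(pos), d[-1])
  aperm(out, order(perm))
}

#' Trilinear (or nearest-neighbor) resampling of a 3-D array
#'
#' Either an explicit output shape (`dim_out`; corners aligned) or an
#' input/output spacing pair (`(z, y, x)` order; grids share the position of
#' voxel 0) defines the output grid.
#'
#' @param arr 3-D array, `(z, y, x)` order.
#' @param spacing_in,spacing_out spacings in mm, `(z, y, x)` order.
#' @param dim_out explicit output shape (overrides spacings).
#' @param mode `"linear"` or `"nearest"` (use nearest for masks).
#' @return resampled array.
#' @export
resample_trilinear <- function(arr, spacing_in = NULL, spacing_out = NULL,
                               dim_out = NULL, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(arr)
  stopifnot(length(d) == 3L)
  if (is.null(dim_out)) {
    stopifnot(!is.null(spacing_in), !is.null(spacing_out))
    dim_out <- pmax(1L, as.integer(round((d - 1) * spacing_in /
                                           spacing_out)) + 1L)
    pos <- lapply(1:3, function(ax) {
      1 + (seq_len(dim_out[ax]) - 1) * spacing_out[ax] / spacing_in[ax]
    })
  } else {
    dim_out <- as.integer(dim_out)
    pos <- lapply(1:3, function(ax) {
      if (dim_out[ax] == 1L) 1
      else 1 + (seq_len(dim_out[ax]) - 1) * (d[ax] - 1) / (dim_out[ax] - 1)
    })
  }
  out <- arr
  for (ax in 1:3) out <- interp_axis3(out, ax, pos[[ax]], mode)
  out
}

#' Preprocess a CT volume
#'
#' The pipeline: (1) multiply by the binary lung mask; (2) clip to the
#' Hounsfield window and min-max scale the masked voxels to `[0, 1]`
#' (background stays exactly 0); (3) subtract the mean over masked voxels
#' (within the mask only, so background zeros neither bias the mean nor get
#' shifted); (4) optionally resample to the target spacing, trilinear for
#' the image and nearest-neighbor for the mask. Stages 1-3 are idempotent:
#' re-applying them to their own output with the same mask is a no-op.
#'
#' @param vol a [ct_volume()].
#' @param lung_mask binary array of the volume's shape.
#' @param cfg a [preprocess_config()].
#' @param resample set to FALSE to skip stage 4.
#' @return list with `volume` (preprocessed [ct_volume()]) and `mask` (the
#'   lung mask on the output grid).
#' @export
preprocess_volume <- function(vol, lung_mask, cfg = preprocess_config(),
                              resample = TRUE) {
  if (!identical(dim(vol$voxels), dim(lung_mask))) {
    stop("preprocess_volume: mask shape (",
         paste(dim(lung_mask), collapse = "x"),
         ") does not match volume shape (",
         paste(dim(vol$voxels), collapse = "x"), ")")
  }
  v <- vol$voxels * (lung_mask > 0)
  inside <- lung_mask > 0
  if (any(inside)) {
    w <- pmin(pmax(v[inside], cfg$hu_window[1]), cfg$hu_window[2])
    rng <- range(w)
    w <- if (rng[2] > rng[1]) (w - rng[1]) / (rng[2] - rng[1]) else w * 0
    w <- w - mean(w)
    v[inside] <- w
    v[!inside] <- 0
  }
  spacing_zyx <- rev(vol$spacing)
  if (resample && !isTRUE(all.equal(spacing_zyx, cfg$target_spacing))) {
    vr <- resample_trilinear(v, spacing_zyx, cfg$target_spacing)
    mr <- resample_trilinear(lung_mask, spacing_zyx, cfg$target_spacing,
                             mode = "nearest")
    out <- ct_volume(vr, origin = vol$origin,
                     spacing = rev(cfg$target_spacing),
                     series_id = vol$series_id)
    return(list(volume = out, mask = mr))
  }
  list(volume = ct_volume(v, origin = vol$origin, spacing = vol$spacing,
                          series_id = vol$series_id),
       mask = lung_mask)
}

#' Extract an ROI patch pair around a nodule annotation
#'
#' Crops a `patch_shape` region (half-open index ranges) centered on the
#' annotation's voxel center, zero-padding symmetrically where the crop
#' leaves the volume.
#'
#' @param vol preprocessed [ct_volume()].
#' @param nodule_mask binary array of the volume's shape.
#' @param ann one-row data.frame with `coordX`, `coordY`, `coordZ` (mm) and
#'   `diameter_mm`.
#' @param patch_shape integer `(z, y, x)` patch shape.
#' @return list with `image`, `mask` (arrays of `patch_shape`) and
#'   `provenance` (`series_id`, center voxel).
#' @export
extract_patch <- function(vol, nodule_mask, ann,
                          patch_shape = c(16L, 96L, 96L)) {
  stopifnot(identical(dim(vol$voxels), dim(nodule_mask)))
  ctr <- world_to_voxel(c(ann$coordX, ann$coordY, ann$coordZ), vol)  # (z,y,x)
  d <- dim(vol$voxels)
  ps <- as.integer(patch_shape)
  start <- ctr - ps %/% 2L                 # 0-based, half-open [start, start+ps)
  img <- array(0, ps); msk <- array(0, ps)
  src_lo <- pmax(start, 0L); src_hi <- pmin(start + ps, d)
  if (any(src_lo >= src_hi)) {
    stop("extract_patch: annotation center (", paste(ctr, collapse = ", "),
         ") leaves no overlap with the volume")
  }
  dst_lo <- src_lo - start
  sl <- function(lo, hi) (lo + 1L):hi
  img[sl(dst_lo[1], dst_lo[1] + src_hi[1] - src_lo[1]),
      sl(dst_lo[2], dst_lo[2] + src_hi[2] - src_lo[2]),
      sl(dst_lo[3], dst_lo[3] + src_hi[3] - src_lo[3])] <-
    vol$voxels[sl(src_lo[1], src_hi[1]), sl(src_lo[2], src_hi[2]),
               sl(src_lo[3], src_hi[3])]
  msk[sl(dst_lo[1], dst_lo[1] + src_hi[1] - src_lo[1]),
      sl(dst_lo[2], dst_lo[2] + src_hi[2] - src_lo[2]),
      sl(dst_lo[3], dst_lo[3] + src_hi[3] - src_lo[3])] <-
    nodule_mask[sl(src_lo[1], src_hi[1]), sl(src_lo[2], src_hi[2]),
                sl(src_lo[3], src_hi[3])]
  list(image = img, mask = msk,
       provenance = list(series_id = vol$series_id, center = ctr))
}

# even-odd point-in-polygon for integer pixel grid (vectorized ray casting)
polygon_fill <- function(px, py, nx, ny) {
  xs <- rep(seq_len(nx) - 1L, times = ny)
  ys <- rep(seq_len(ny) - 1L, each = nx)
  inside <- logical(nx * ny)
  np <- length(px)
  j <- np
  for (i in seq_len(np)) {
    crosses <- (py[i] > ys) != (py[j] > ys)
    if (any(crosses)) {
      xint <- px[i] + (ys[crosses] - py[i]) * (px[j] - px[i]) /
        (py[j] - py[i])
      hit <- which(crosses)[xint > xs[crosses]]
      inside[hit] <- !inside[hit]
    }
    j <- i
  }
  m <- matrix(FALSE, nx, ny)
  m[cbind(xs + 1L, ys + 1L)] <- inside
  # boundary pixels are included: rasterize each edge densely
  j <- np
  for (i in seq_len(np)) {
    steps <- max(2L, 2L * ceiling(max(abs(px[i] - px[j]),
                                      abs(py[i] - py[j]))) + 1L)
    t <- seq(0, 1, length.out = steps)
    bx <- round(px[j] + t * (px[i] - px[j])) + 1L
    by <- round(py[j] + t * (py[i] - py[j])) + 1L
    ok <- bx >= 1L & bx <= nx & by >= 1L & by <= ny
    m[cbind(bx[ok], by[ok])] <- TRUE
    j <- i
  }
  m
}

#' Rasterize LIDC XML nodule contours into a binary mask
#'
#' Each reading session contributes a per-slice polygon fill (even-odd rule,
#' edge pixels included) of its ROI edge maps, stacked by matching the ROI's
#' `imageZposition` to a volume slice within half a z-spacing; unmatched
#' positions raise a warning and the slice is skipped. A voxel enters the
#' final mask when at least `consensus` of the reading sessions contain it.
#'
#' @param xml_doc an `xml2` document, node, or a path to the XML file.
#' @param vol a [ct_volume()].
#' @param consensus fraction of readers required (default 0.5).
#' @return binary array of the volume's shape.
#' @export
lidc_contours_to_mask <- function(xml_doc, vol, consensus = 0.5) {
  doc <- if (inherits(xml_doc, "xml_node") || inherits(xml_doc, "xml_document"))
    xml_doc else xml2::read_xml(xml_doc)
  doc <- xml2::xml_ns_strip(doc)
  d <- dim(vol$voxels)                     # (z, y, x)
  z_world <- vol$origin[3] + (seq_len(d[1]) - 1) * vol$spacing[3]
  sessions <- xml2::xml_find_all(doc, ".//readingSession")
  if (length(sessions) == 0L) return(array(0, d))
  reader_masks <- list()
  for (s in sessions) {
    m <- array(FALSE, d)
    rois <- xml2::xml_find_all(s, ".//unblindedReadNodule/roi")
    for (roi in rois) {
      zpos <- as.numeric(xml2::xml_text(
        xml2::xml_find_first(roi, "./imageZposition")))
      xs <- as.numeric(xml2::xml_text(
        xml2::xml_find_all(roi, "./edgeMap/xCoord")))
      ys <- as.numeric(xml2::xml_text(
        xml2::xml_find_all(roi, "./edgeMap/yCoord")))
      if (length(xs) == 0L) next
      zi <- which.min(abs(z_world - zpos))
      if (abs(z_world[zi] - zpos) > vol$spacing[3] / 2 + 1e-9) {
        warning("lidc_contours_to_mask: imageZposition ", zpos,
                " matches no slice; skipping")
        next
      }
      fill <- polygon_fill(xs, ys, d[3], d[2])   # (x, y)
      m[zi, , ] <- m[zi, , ] | t(fill)
    }
    reader_masks[[length(reader_masks) + 1L]] <- m
  }
  votes <- Reduce(`+`, lapply(reader_masks, function(m) m * 1))
  out <- (votes >= consensus * length(reader_masks)) * 1
  dim(out) <- d
  out
}

#' Split series into training and validation subsets
#'
#' @param annotation_table data.frame with `series_id` and `subset` columns.
#' @param train_subsets,val_subsets subset tags per split (defaults 0-7 and
#'   8-9).
#' @return list with disjoint `train_ids` and `val_ids`.
#' @export
split_subsets <- function(annotation_table, train_subsets = 0:7,
                          val_subsets = 8:9) {
  stopifnot(all(c("series_id", "subset") %in% names(annotation_table)))
  known <- c(train_subsets, val_subsets)
  bad <- setdiff(unique(annotation_table$subset), known)
  if (length(bad) > 0L) {
    stop("split_subsets: unknown subset index: ", paste(bad, collapse = ", "))
  }
  train_ids <- unique(
    annotation_table$series_id[annotation_table$subset %in% train_subsets])
  val_ids <- unique(
    annotation_table$series_id[annotation_table$subset %in% val_subsets])
  list(train_ids = train_ids, val_ids = setdiff(val_ids, train_ids))
}

#' Load a generated dataset from disk
#'
#' @param dir directory written by [generate_dataset()].
#' @return list of pairs with `image`, `mask`, `series_id`, `subset`.
#' @export
load_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    list(image = readRDS(file.path(dir, manifest$patch_path[i])),
         mask = readRDS(file.path(dir, manifest$mask_path[i])),
         series_id = manifest$series_id[i],
         subset = manifest$subset[i])
  })
}
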