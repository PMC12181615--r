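# 3D assembly and whole-brain quantification: label-preserving downscaling,
# brain-surface masking, minimum-overlay noise removal, volume stacking, and
# CMH burden metrics.

#' Combine tissue and bleed masks into a 0/1/2 label map
#'
#' @param tissue Logical tissue mask.
#' @param bleed Logical bleed mask (bleed wins where both are set).
#' @return Integer label matrix (0 = background, 1 = tissue, 2 = bleed).
#' @export
masks_to_labels <- function(tissue, bleed) {
  lab <- matrix(0L, nrow(tissue), ncol(tissue))
  lab[tissue] <- 1L
  lab[bleed] <- 2L
  lab
}

block_count <- function(mask, f) {
  nr <- (nrow(mask) %/% f) * f
  nc <- (ncol(mask) %/% f) * f
  x <- mask[seq_len(nr), seq_len(nc)] * 1
  x <- rowsum(x, rep(seq_len(nr %/% f), each = f))
  t(rowsum(t(x), rep(seq_len(nc %/% f), each = f)))
}

#' Downscale a label stack by block majority vote
#'
#' Each `factor x factor` block takes the majority class; ties break toward
#' the higher code so small bleeds survive the reduction. Pixel size is
#' scaled accordingly.
#'
#' @param stack A `cmh_stack` of integer label maps.
#' @param factor Integer reduction factor (default 5, the volumetric
#'   rendering reduction); must not exceed the canvas.
#' @return The downscaled `cmh_stack`.
#' @export
downscale_stack <- function(stack, factor = 5L) {
  stopifnot(inherits(stack, "cmh_stack"))
  factor <- as.integer(factor)
  if (factor < 1L) stop_config("factor must be >= 1")
  if (factor > min(stack$canvas)) {
    stop_config("downscale factor larger than the image")
  }
  if (factor == 1L) return(stack)
  images <- lapply(stack$images, function(lab) {
    counts <- lapply(0:2, function(k) block_count(lab == k, factor))
    win <- matrix(0L, nrow(counts[[1]]), ncol(counts[[1]]))
    best <- counts[[1]]
    for (k in 1:2) {
      take <- counts[[k + 1L]] >= best
      win[take] <- k
      best[take] <- counts[[k + 1L]][take]
    }
    win
  })
  out <- new_stack(images, stack$pixel_size_um * factor, NULL)
  out$transforms <- stack$transforms
  out
}

#' Build a smooth 3D brain-surface mask
#'
#' Stand-in for interactive surface segmentation: the per-section occupancy
#' field (tissue or bleed) is Gaussian-smoothed in 3D (sigma in voxels),
#' thresholded at 0.5, and reduced to its largest 6-connected 3D component,
#' yielding one closed smooth envelope of the brain.
#'
#' @param stack A `cmh_stack` of label maps (aligned).
#' @param sigma Smoothing sigma in voxels (default 2).
#' @param threshold Occupancy threshold (default 0.5).
#' @return List of logical per-section masks.
#' @export
build_brain_mask <- function(stack, sigma = 2, threshold = 0.5) {
  stopifnot(inherits(stack, "cmh_stack"))
  nz <- length(stack$images)
  if (nz == 0L) stop_data("empty stack")
  nr <- stack$canvas[1]
  nc <- stack$canvas[2]
  occ <- lapply(stack$images, function(lab) {
    gaussian_blur((lab > 0L) * 1.0, sigma)
  })
  if (nz > 1L && sigma > 0) {
    zmat <- blur1d_matrix(nz, sigma)
    flat <- do.call(rbind, lapply(occ, as.vector)) # nz x npx
    flat <- zmat %*% flat
    occ <- lapply(seq_len(nz), function(z) matrix(flat[z, ], nr, nc))
  }
  arr <- array(FALSE, c(nz, nr, nc))
  for (z in seq_len(nz)) arr[z, , ] <- occ[[z]] > threshold
  if (!any(arr)) return(lapply(seq_len(nz), function(z) matrix(FALSE, nr, nc)))
  lab3 <- cpp_label_components_3d(as.vector(arr), nz, nr, nc)
  counts <- tabulate(lab3[lab3 > 0L])
  keep <- which.max(counts)
  arr3 <- array(lab3 == keep, c(nz, nr, nc))
  lapply(seq_len(nz), function(z) matrix(arr3[z, , ], nr, nc))
}

#' Zero label codes outside the brain mask
#'
#' Voxelwise minimum with the mask's code ceiling: codes outside the brain
#' envelope are forced to 0 (removing extratissular noise), codes inside are
#' unchanged. Never increases any code.
#'
#' @param stack A `cmh_stack` of label maps.
#' @param mask List of logical per-section masks from [build_brain_mask()].
#' @return The masked `cmh_stack`.
#' @export
minimum_overlay <- function(stack, mask) {
  stopifnot(inherits(stack, "cmh_stack"))
  if (length(mask) != length(stack$images)) {
    stop_data("mask and stack section counts differ")
  }
  images <- lapply(seq_along(stack$images), function(i) {
    lab <- stack$images[[i]]
    m <- mask[[i]]
    if (!all(dim(m) == dim(lab))) stop_data("mask dimensions do not match stack")
    pmin(lab, ifelse(m, 2L, 0L))
  })
  out <- new_stack(images, stack$pixel_size_um, stack$transforms)
  out
}

#' Stack aligned sections into a labeled brain volume
#'
#' @param stack A `cmh_stack` of label maps (aligned, masked).
#' @param z_spacing_um Section-to-section spacing in um. The default 20
#'   corresponds to 8-um sections with a 2-of-5 retention scheme (mean
#'   spacing 8 x 5/2).
#' @return Object of class `cmh_volume`: integer array `(z, rows, cols)` with
#'   attributes `voxel_size_um = c(z, y, x)` and `pixel_size_um`.
#' @export
assemble_volume <- function(stack, z_spacing_um = 20) {
  stopifnot(inherits(stack, "cmh_stack"))
  dims <- vapply(stack$images, function(x) dim(x)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_data("inconsistent canvas sizes in stack")
  }
  nz <- length(stack$images)
  vol <- array(0L, c(nz, dims[1, 1], dims[2, 1]))
  for (z in seq_len(nz)) vol[z, , ] <- stack$images[[z]]
  structure(
    vol,
    voxel_size_um = c(z = z_spacing_um, y = stack$pixel_size_um,
                      x = stack$pixel_size_um),
    pixel_size_um = stack$pixel_size_um,
    class = "cmh_volume"
  )
}

#' @export
print.cmh_volume <- function(x, ...) {
  d <- dim(x)
  vs <- attr(x, "voxel_size_um")
  cat(sprintf(
    "Brain volume: %d x %d x %d voxels (%.1f x %.2f x %.2f um), depth %.2f mm\n",
    d[1], d[2], d[3], vs[1], vs[2], vs[3], d[1] * vs[1] / 1000
  ))
  invisible(x)
}

#' Count 3D-connected bleed objects in a volume
#'
#' 6-connected labeling of code-2 voxels; merging across sections can only
#' reduce the count relative to per-section 2D objects.
#'
#' @param volume A `cmh_volume`.
#' @return Number of 3D bleed components.
#' @export
count_bleed_objects_3d <- function(volume) {
  d <- dim(volume)
  lab <- cpp_label_components_3d(as.vector(volume == 2L), d[1], d[2], d[3])
  attr(lab, "n")
}

#' Maximum-intensity code projection of a volume
#'
#' @param volume A `cmh_volume`.
#' @param path Optional PNG path; tissue renders blue, bleeds pink.
#' @return Invisibly, the projected code matrix.
#' @export
max_projection <- function(volume, path = NULL) {
  proj <- apply(unclass(volume), c(2, 3), max)
  if (!is.null(path)) {
    rgb <- array(1, c(nrow(proj), ncol(proj), 3))
    rgb[, , 1][proj == 1L] <- 0.55
    rgb[, , 2][proj == 1L] <- 0.65
    rgb[, , 1][proj == 2L] <- 1
    rgb[, , 2][proj == 2L] <- 0.3
    rgb[, , 3][proj == 2L] <- 0.6
    png::writePNG(rgb, path)
  }
  invisible(proj)
}

#' Quantify CMH burden in a labeled stack or volume
#'
#' Per section: tissue cross-section area in mm^2 (tissue + bleed pixels),
#' bleed area (um^2) and area fraction (% of tissue), bleed object count
#' (2D particle analysis, matching per-section histological counting), and
#' density (objects per mm^2 tissue). The aggregate row pools pixels and
#' counts, i.e. tissue-area-weighted means.
#'
#' @param x A `cmh_stack` of label maps or a `cmh_volume`.
#' @param pixel_size_um Pixel calibration; taken from `x` when available.
#' @param min_area_um2,connectivity Passed to [analyze_particles()].
#' @return Data frame of class `cmh_quant`: one row per section plus an
#'   aggregate row (`section = NA`), columns `tissue_area_mm2`,
#'   `bleed_area_um2`, `area_fraction_pct`, `count`, `density_per_mm2`.
#' @export
quantify_cmh <- function(x, pixel_size_um = NULL, min_area_um2 = 10,
                         connectivity = 8L) {
  if (inherits(x, "cmh_volume")) {
    ps <- pixel_size_um %||% attr(x, "pixel_size_um")
    sections <- lapply(seq_len(dim(x)[1]), function(z) {
      matrix(x[z, , ], dim(x)[2], dim(x)[3])
    })
  } else if (inherits(x, "cmh_stack")) {
    ps <- pixel_size_um %||% x$pixel_size_um
    sections <- x$images
  } else {
    stop_data("x must be a cmh_stack or cmh_volume")
  }
  rows <- lapply(seq_along(sections), function(i) {
    lab <- sections[[i]]
    tissue_px <- sum(lab >= 1L)
    parts <- analyze_particles(lab == 2L, ps, min_area_um2, connectivity)
    bleed_area <- sum(parts$area_um2)
    tissue_mm2 <- tissue_px * (ps / 1000)^2
    data.frame(
      section = i,
      tissue_area_mm2 = tissue_mm2,
      bleed_area_um2 = bleed_area,
      area_fraction_pct = if (tissue_px > 0) {
        100 * bleed_area / (tissue_px * ps^2)
      } else NA_real_,
      count = nrow(parts),
      density_per_mm2 = if (tissue_mm2 > 0) nrow(parts) / tissue_mm2 else NA_real_
    )
  })
  df <- do.call(rbind, rows)
  tot_tissue <- sum(df$tissue_area_mm2)
  if (tot_tissue <= 0) stop_degenerate("zero tissue area: nothing to quantify")
  agg <- data.frame(
    section = NA_integer_,
    tissue_area_mm2 = tot_tissue,
    bleed_area_um2 = sum(df$bleed_area_um2),
    area_fraction_pct = 100 * sum(df$bleed_area_um2) / (tot_tissue * 1e6),
    count = sum(df$count),
    density_per_mm2 = sum(df$count) / tot_tissue
  )
  out <- rbind(df, agg)
  attr(out, "pixel_size_um") <- ps
  class(out) <- c("cmh_quant", "data.frame")
  out
}

#' @export
print.cmh_quant <- function(x, ...) {
  agg <- x[is.na(x$section), ]
  cat(sprintf(
    paste0("CMH burden: %d objects over %.2f mm2 tissue ",
           "(%.4f%% area, %.2f /mm2)\n"),
    agg$count, agg$tissue_area_mm2, agg$area_fraction_pct,
    agg$density_per_mm2
  ))
  invisible(x)
}

#' Write a brain volume as a multi-page TIFF with voxel metadata sidecar
#'
#' @param volume A `cmh_volume`.
#' @param path Output TIFF; a JSON sidecar stores the voxel size.
#' @return Invisibly, `path`.
#' @export
write_volume_tiff <- function(volume, path) {
  pages <- lapply(seq_len(dim(volume)[1]), function(z) {
    matrix(volume[z, , ] / 255, dim(volume)[2], dim(volume)[3])
  })
  tiff::writeTIFF(pages, path)
  jsonlite::write_json(
    as.list(attr(volume, "voxel_size_um")),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}
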