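# Semi-automated segmentation: bandpass filtering, Otsu thresholding,
# binarization, hole filling, particle analysis, and the two per-image
# methods (HDAB deconvolution track and YIQ chrominance track).

#' Difference-of-Gaussians bandpass filter
#'
#' Suppresses structures larger than `large_size_px` and smaller than
#' `small_size_px`: `G(sigma_small) * img - G(sigma_large) * img` with
#' `sigma = size / 2`. The result is offset and rescaled into the input's
#' value range so downstream histogram thresholding sees non-negative values.
#'
#' @param channel Numeric matrix (one image channel).
#' @param large_size_px Structures larger than this are suppressed.
#' @param small_size_px Structures smaller than this are suppressed;
#'   must satisfy `large_size_px > small_size_px > 0`.
#' @return Filtered matrix in the input's value range.
#' @export
bandpass_filter <- function(channel, large_size_px = 50, small_size_px = 2) {
  if (!(large_size_px > small_size_px && small_size_px > 0)) {
    stop_config("bandpass sizes must satisfy large > small > 0")
  }
  if (!is.matrix(channel)) stop_format("channel must be a matrix")
  d <- gaussian_blur(channel, small_size_px / 2) -
    gaussian_blur(channel, large_size_px / 2)
  lo <- min(channel)
  hi <- max(channel)
  dl <- min(d)
  dh <- max(d)
  if (dh - dl < .Machine$double.eps * max(1, abs(dh))) {
    # flat AC component: constant input stays constant
    return(matrix(lo, nrow(channel), ncol(channel)))
  }
  (d - dl) / (dh - dl) * (hi - lo) + lo
}

#' Otsu's threshold
#'
#' Builds an `n_bins` histogram over the channel's `[min, max]` range and
#' returns the interior bin edge maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`. Ties are broken by the lowest threshold.
#' Float channels are binned, not truncated.
#'
#' @param channel Numeric matrix or vector with at least two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold (a bin edge): pixels with value <= threshold fall in
#'   the lower class.
#' @export
otsu_threshold <- function(channel, n_bins = 256L) {
  v <- as.numeric(channel)
  v <- v[is.finite(v)]
  lo <- min(v)
  hi <- max(v)
  if (hi - lo <= 1e-9 * max(abs(lo), abs(hi), 1)) {
    stop_degenerate("constant channel: Otsu threshold undefined")
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  # bin index in 1..n_bins; right-closed except the first bin
  bin <- pmin(pmax(ceiling((v - lo) / (hi - lo) * n_bins), 1L), n_bins)
  h <- tabulate(bin, nbins = n_bins)
  p <- h / sum(h)
  w0 <- cumsum(p)[-n_bins]
  mu <- cumsum(p * (seq_len(n_bins) - 0.5))
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  num <- mu_t * w0 - mu[-n_bins]
  sb <- ifelse(valid, num^2 / (w0 * w1), -Inf)
  k <- which.max(sb) # which.max returns the first (lowest) maximizer
  if (!is.finite(sb[k])) stop_degenerate("degenerate histogram for Otsu")
  edges[k + 1L]
}

#' Binarize a channel against a threshold
#'
#' @param channel Numeric matrix.
#' @param threshold Threshold value.
#' @param polarity `"bright"`: foreground where value > threshold;
#'   `"dark"`: foreground where value < threshold.
#' @return Logical matrix (the binary mask).
#' @export
binarize <- function(channel, threshold, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (polarity == "bright") channel > threshold else channel < threshold
}

#' Fill enclosed holes in a binary mask
#'
#' Background components not connected to the image border become foreground;
#' foreground is never removed. Background connectivity is 4 (the dual of the
#' default 8-connected foreground).
#'
#' @param mask Logical matrix.
#' @return Logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0
  bg <- cpp_label_components(!mask, 4L)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0L]
  mask | (bg > 0L & !(bg %in% border_labels))
}

#' Particle analysis of a binary mask
#'
#' Connected-component labeling followed by per-object measurement, the
#' histology-style "count and measure every blob" step. Objects smaller than
#' `min_area_um2` are dropped.
#'
#' @param mask Logical matrix (foreground = candidate microbleed).
#' @param pixel_size_um Pixel calibration (um/px, > 0).
#' @param min_area_um2 Minimum object area kept, in um^2 (default 10, about
#'   1-4 px at the default calibration; drops single-pixel noise).
#' @param connectivity 4 or 8 (default 8, the common particle-analysis
#'   convention).
#' @return Data frame of class `cmh_particles`: `object_id`, `pixels`,
#'   `area_um2`, `centroid_row`, `centroid_col`, `eq_diameter_um`,
#'   `bbox_rmin`, `bbox_rmax`, `bbox_cmin`, `bbox_cmax`. Attributes record
#'   `pixel_size_um`, `connectivity`, `dropped_pixels` (foreground pixels in
#'   dropped objects) and the label matrix (`labels`).
#' @export
analyze_particles <- function(mask, pixel_size_um, min_area_um2 = 10,
                              connectivity = 8L) {
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop_config("pixel_size_um must be > 0")
  }
  if (!connectivity %in% c(4L, 8L)) stop_config("connectivity must be 4 or 8")
  if (!is.logical(mask)) mask <- mask > 0
  lab <- cpp_label_components(mask, as.integer(connectivity))
  n <- max(lab)
  empty <- data.frame(
    object_id = integer(), pixels = integer(), area_um2 = numeric(),
    centroid_row = numeric(), centroid_col = numeric(),
    eq_diameter_um = numeric(), bbox_rmin = integer(), bbox_rmax = integer(),
    bbox_cmin = integer(), bbox_cmax = integer()
  )
  if (n == 0L) {
    out <- empty
    dropped <- 0L
  } else {
    idx <- which(lab > 0L)
    ids <- lab[idx]
    rows <- (idx - 1L) %% nrow(lab) + 1L
    cols <- (idx - 1L) %/% nrow(lab) + 1L
    npx <- tabulate(ids, nbins = n)
    area <- npx * pixel_size_um^2
    keep <- area >= min_area_um2
    dropped <- sum(npx[!keep])
    out <- data.frame(
      object_id = seq_len(n),
      pixels = npx,
      area_um2 = area,
      centroid_row = rowsum(as.numeric(rows), ids)[, 1] / npx,
      centroid_col = rowsum(as.numeric(cols), ids)[, 1] / npx,
      eq_diameter_um = 2 * sqrt(area / pi),
      bbox_rmin = as.integer(tapply(rows, ids, min)),
      bbox_rmax = as.integer(tapply(rows, ids, max)),
      bbox_cmin = as.integer(tapply(cols, ids, min)),
      bbox_cmax = as.integer(tapply(cols, ids, max))
    )[keep, , drop = FALSE]
    rownames(out) <- NULL
    out$object_id <- seq_len(nrow(out))
    lab[lab %in% which(!keep)] <- 0L
    relab <- integer(n)
    relab[which(keep)] <- seq_len(sum(keep))
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  attr(out, "pixel_size_um") <- pixel_size_um
  attr(out, "connectivity") <- as.integer(connectivity)
  attr(out, "dropped_pixels") <- if (n == 0L) 0L else dropped
  attr(out, "labels") <- lab
  class(out) <- c("cmh_particles", "data.frame")
  out
}

#' Segment microbleeds by HDAB color deconvolution
#'
#' The deconvolution track: optical density, HDAB unmixing, DAB channel,
#' difference-of-Gaussians bandpass (default sizes 50/2 px in processed-image
#' pixels), Otsu threshold (bright polarity: more DAB = higher value), and
#' hole filling. An all-background (blank) image yields an empty mask rather
#' than an error.
#'
#' This track is stain-aware but threshold-naive: dense achromatic debris has
#' a large positive DAB component after unmixing, so artifact-rich slides are
#' over-counted - the behaviour that motivates the YIQ and classifier tracks.
#'
#' @param image RGB array.
#' @param params Optional list overriding `bandpass_large` (50),
#'   `bandpass_small` (2), `stains`, `i0`.
#' @return Logical mask with attributes `method = "hdab"`, `threshold`, and
#'   `params`.
#' @export
segment_hdab <- function(image, params = list()) {
  check_rgb(image)
  p <- utils::modifyList(list(
    bandpass_large = 50, bandpass_small = 2,
    stains = hdab_stain_matrix(), i0 = c(255, 255, 255)
  ), params)
  od <- rgb_to_od(image, p$i0)
  conc <- deconvolve_stains(od, p$stains)
  dab <- conc[, , 2]
  filtered <- bandpass_filter(dab, p$bandpass_large, p$bandpass_small)
  thr <- tryCatch(otsu_threshold(filtered), cmhq_degenerate_error = function(e) NULL)
  if (is.null(thr)) {
    mask <- matrix(FALSE, nrow(dab), ncol(dab))
    thr <- NA_real_
  } else {
    mask <- fill_holes(binarize(filtered, thr, "bright"))
  }
  structure(mask, method = "hdab", threshold = thr, params = p)
}

#' Luma-based tissue mask
#'
#' Pixels darker than the Otsu threshold of the Y (luma) channel: stained
#' tissue (and any bleeds and debris on it) against the bright slide
#' background.
#'
#' @param image RGB array.
#' @return Logical matrix; empty if the luma channel is constant (blank
#'   slide).
#' @export
tissue_mask_luma <- function(image) {
  check_rgb(image)
  y <- rgb_to_yiq(image)[, , 1]
  thr <- tryCatch(otsu_threshold(y), cmhq_degenerate_error = function(e) NULL)
  if (is.null(thr)) return(matrix(FALSE, nrow(y), ncol(y)))
  binarize(y, thr, "dark")
}

#' Segment microbleeds by YIQ chrominance
#'
#' The color-space track: the image is converted to YIQ and the in-phase (I)
#' chrominance channel - orange positive, blue negative - is Otsu-thresholded
#' with bright polarity, then hole-filled. By default the threshold is
#' computed over tissue pixels only (luma-restricted) and floored at the
#' achromatic noise level: white background sits at I = 0, *between* the blue
#' tissue mode and the orange DAB mode, so an unrestricted histogram would
#' latch onto the tissue/background boundary instead of the bleeds, and DAB
#' is by construction on the positive (orange) side of the achromatic axis.
#' The floor is three times the normal-consistent MAD of I over background
#' pixels (exactly 0 for noise-free input), so sensor noise and gray debris
#' at the achromatic axis never cross the threshold. Set `tissue_restrict = FALSE` for the raw
#' unrestricted behaviour.
#'
#' @param image RGB array.
#' @param params Optional list overriding `tissue_restrict` (TRUE),
#'   `zero_floor` (TRUE; floor the threshold at the background achromatic
#'   noise level), `yiq` (the transform matrix).
#' @return Logical mask with attributes `method = "yiq"`, `threshold`,
#'   `params`.
#' @export
segment_yiq <- function(image, params = list()) {
  check_rgb(image)
  p <- utils::modifyList(
    list(tissue_restrict = TRUE, zero_floor = TRUE, yiq = yiq_matrix()),
    params
  )
  yiq <- rgb_to_yiq(image, p$yiq)
  ichan <- yiq[, , 2]
  if (p$tissue_restrict) {
    tissue <- tissue_mask_luma(image)
    if (!any(tissue)) {
      return(structure(matrix(FALSE, nrow(ichan), ncol(ichan)),
                       method = "yiq", threshold = NA_real_, params = p))
    }
    thr <- otsu_threshold(ichan[tissue])
    if (p$zero_floor) {
      noise <- if (any(!tissue)) stats::mad(ichan[!tissue]) else 0
      thr <- max(thr, 3 * noise, 0)
    }
    mask <- binarize(ichan, thr, "bright") & tissue
  } else {
    thr <- otsu_threshold(ichan)
    if (p$zero_floor) thr <- max(thr, 0)
    mask <- binarize(ichan, thr, "bright")
  }
  mask <- fill_holes(mask)
  structure(mask, method = "yiq", threshold = thr, params = p)
}

#' Write a binary mask as an 8-bit 0/255 TIFF
#'
#' @param mask Logical matrix.
#' @param path Output file. A JSON sidecar `<path>.json` records the method
#'   provenance attributes if present.
#' @return Invisibly, `path`.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF((mask > 0) * 1.0, path)
  meta <- list(
    method = attr(mask, "method"),
    threshold = attr(mask, "threshold")
  )
  if (!is.null(meta$method)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}
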