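# Color-domain transforms: Beer-Lambert optical density, HDAB stain
# deconvolution, and the NTSC YIQ color space.

#' Default HDAB stain matrix
#'
#' Returns the 3x3 stain optical-density matrix used for hematoxylin/DAB
#' unmixing. Rows are stains (hematoxylin, DAB, residual), columns are RGB
#' channels. The hematoxylin and DAB rows are the Ruifrok-Johnston vectors
#' popularized by the ImageJ "H DAB" preset; the residual row is the
#' normalized cross product of the two, so the matrix is invertible but not
#' orthonormal. Every row has unit Euclidean norm.
#'
#' @return A 3x3 numeric matrix with rownames `c("hematoxylin", "dab",
#'   "residual")` and unit-norm rows.
#' @examples
#' M <- hdab_stain_matrix()
#' rowSums(M^2) # all 1
#' @export
hdab_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  h <- h / sqrt(sum(h^2))
  d <- d / sqrt(sum(d^2))
  r <- c(
    h[2] * d[3] - h[3] * d[2],
    h[3] * d[1] - h[1] * d[3],
    h[1] * d[2] - h[2] * d[1]
  )
  r <- r / sqrt(sum(r^2))
  m <- rbind(h, d, r)
  dimnames(m) <- list(c("hematoxylin", "dab", "residual"), c("R", "G", "B"))
  m
}

check_stain_matrix <- function(stains) {
  if (!is.matrix(stains) || any(dim(stains) != c(3L, 3L))) {
    stop_config("stain matrix must be 3x3 (rows = stains, cols = RGB)")
  }
  norms <- sqrt(rowSums(stains^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop_config("stain matrix rows must have unit Euclidean norm")
  }
  if (abs(det(stains)) < 1e-8) stop_linalg("stain matrix is singular")
  invisible(stains)
}

#' Convert an RGB brightfield image to optical density
#'
#' Beer-Lambert transform `OD_c = -log10(max(I_c, 1) / I0_c)` per channel,
#' where `I0` is the incident (background) intensity. Intensities are clipped
#' to at least 1 before the logarithm so fully extinguished pixels stay
#' finite; a pixel exactly at `I0` has OD 0.
#'
#' @param image RGB array (rows x cols x 3), 8-bit scale (0-255).
#' @param i0 Per-channel reference intensity in (0, 255]; length 1 or 3.
#'   Default `c(255, 255, 255)`. Use [estimate_background()] for per-slide
#'   estimation.
#' @return Numeric array of per-channel optical densities with attribute
#'   `i0`.
#' @examples
#' od <- rgb_to_od(array(255, c(2, 2, 3)))
#' all(od == 0)
#' @export
rgb_to_od <- function(image, i0 = c(255, 255, 255)) {
  check_rgb(image)
  i0 <- rep_len(as.numeric(i0), 3L)
  if (any(!is.finite(i0)) || any(i0 <= 0) || any(i0 > 255)) {
    stop_config("i0 must be per-channel intensities in (0, 255]")
  }
  od <- image
  for (k in 1:3) od[, , k] <- -log10(pmax(image[, , k], 1) / i0[k])
  attr(od, "i0") <- i0
  od
}

#' Estimate per-slide background intensity
#'
#' The 99th-percentile intensity of each channel, a robust stand-in for the
#' unstained glass background of a slide.
#'
#' @param image RGB array.
#' @return Length-3 numeric vector usable as `i0` in [rgb_to_od()].
#' @export
estimate_background <- function(image) {
  check_rgb(image)
  pmax(vapply(1:3, function(k) quantile(image[, , k], 0.99, names = FALSE), 0), 1)
}

#' Unmix optical densities into stain concentrations
#'
#' Per-pixel linear unmixing: the OD vector is multiplied by the inverse of
#' the stain matrix, giving concentrations in the order (hematoxylin, DAB,
#' residual). Negative concentrations are preserved for diagnostics; no
#' clipping is applied.
#'
#' @param od Optical-density array from [rgb_to_od()].
#' @param stains Stain matrix (rows = stains); default [hdab_stain_matrix()].
#' @return Array (rows x cols x 3) of stain concentrations.
#' @examples
#' M <- hdab_stain_matrix()
#' od <- array(0.7 * M[1, ], c(1, 1, 3))
#' round(deconvolve_stains(od, M), 6) # (0.7, 0, 0)
#' @export
deconvolve_stains <- function(od, stains = hdab_stain_matrix()) {
  check_stain_matrix(stains)
  d <- dim(od)
  if (length(d) != 3L || d[3] != 3L) stop_format("od must be rows x cols x 3")
  inv <- solve(stains)
  flat <- matrix(od, ncol = 3L) %*% inv # forward model is OD = conc %*% M
  conc <- array(flat, d)
  dimnames(conc) <- NULL
  conc
}

#' Render an RGB image from stain concentrations
#'
#' Forward Beer-Lambert model: `I_c = I0_c * 10^(-sum_s conc_s * M[s, c])`.
#' This is the exact inverse of [rgb_to_od()] + [deconvolve_stains()] when
#' quantization is disabled, which the synthetic slide generator exploits.
#'
#' @param conc Concentration array (rows x cols x 3), non-negative.
#' @param stains Stain matrix; default [hdab_stain_matrix()].
#' @param i0 Background intensity per channel (default 255).
#' @param quantize Round to 8-bit integers and clip to \[0, 255\] (default
#'   TRUE). Set FALSE for float output when testing algebraic round trips.
#' @return RGB array.
#' @export
reconstruct_rgb <- function(conc, stains = hdab_stain_matrix(),
                            i0 = c(255, 255, 255), quantize = TRUE) {
  check_stain_matrix(stains)
  d <- dim(conc)
  if (length(d) != 3L || d[3] != 3L) stop_format("conc must be rows x cols x 3")
  i0 <- rep_len(as.numeric(i0), 3L)
  od <- matrix(conc, ncol = 3L) %*% stains
  img <- array(0, d)
  for (k in 1:3) {
    ch <- i0[k] * 10^(-od[, k])
    if (quantize) ch <- pmin(pmax(round(ch), 0), 255)
    img[, , k] <- ch
  }
  img
}

#' NTSC YIQ transform matrix
#'
#' The classic NTSC RGB-to-YIQ matrix (the convention of ImageJ's "Color
#' Transformer 2" plugin). Exposed so dialect variants can be swapped in.
#'
#' @return 3x3 numeric matrix with rows Y, I, Q.
#' @export
yiq_matrix <- function() {
  matrix(c(
    0.299, 0.587, 0.114,
    0.596, -0.274, -0.322,
    0.211, -0.523, 0.312
  ), nrow = 3, byrow = TRUE, dimnames = list(c("Y", "I", "Q"), c("R", "G", "B")))
}

#' Convert an RGB image to the YIQ color space
#'
#' Linear transform `[Y I Q]' = M [R G B]'` with the NTSC matrix. Y is luma;
#' I is the in-phase chrominance axis (orange positive, blue negative), the
#' channel that separates brown DAB deposits from blue hematoxylin tissue.
#' Output is float; no quantization or offset is applied.
#'
#' @param image RGB array (rows x cols x 3).
#' @param m Transform matrix, default [yiq_matrix()].
#' @return Array (rows x cols x 3) with channels Y, I, Q.
#' @examples
#' yiq <- rgb_to_yiq(array(rep(128, 12), c(2, 2, 3)))
#' max(abs(yiq[, , 2])) < 1e-3 # achromatic: zero chrominance
#' @export
rgb_to_yiq <- function(image, m = yiq_matrix()) {
  check_rgb(image)
  flat <- matrix(image, ncol = 3L) %*% t(m)
  array(flat, dim(image))
}
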