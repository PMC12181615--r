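# Internal helpers: error conditions, seeded RNG, separable filters.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Typed conditions so callers (and tests) can distinguish failure modes.
cmhq_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "cmhq_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
stop_config     <- function(msg) cmhq_stop(msg, "cmhq_config_error")
stop_data       <- function(msg) cmhq_stop(msg, "cmhq_data_error")
stop_degenerate <- function(msg) cmhq_stop(msg, "cmhq_degenerate_error")
stop_format     <- function(msg) cmhq_stop(msg, "cmhq_format_error")
stop_linalg     <- function(msg) cmhq_stop(msg, "cmhq_linalg_error")
stop_training   <- function(msg) cmhq_stop(msg, "cmhq_training_error")
stop_inference  <- function(msg) cmhq_stop(msg, "cmhq_inference_error")
stop_stats      <- function(msg) cmhq_stop(msg, "cmhq_stats_error")

# Deterministic sub-stream seeds (kept below 2^31 - 1).
derive_seed <- function(base, ...) {
  idx <- c(...)
  s <- as.double(base) %% 2147483647
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[k]) * 9973 + k) %% 2147483647
  }
  as.integer(s)
}

with_seed <- function(seed, code) withr::with_seed(seed, code)

is_rgb_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L && is.numeric(x)
}

check_rgb <- function(image) {
  if (!is_rgb_image(image)) {
    stop_format("expected an RGB image: numeric array with dim (rows, cols, 3)")
  }
  invisible(image)
}

# --- separable Gaussian filtering ------------------------------------------
# Blur matrices (replicate boundary) are cached per (n, sigma): images in a
# stack share dimensions, so each matrix is built once.

.blur_cache <- new.env(parent = emptyenv())

blur1d_matrix <- function(n, sigma) {
  key <- sprintf("%d_%g", n, sigma)
  got <- .blur_cache[[key]]
  if (!is.null(got)) return(got)
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  off <- (-rad):rad
  k <- exp(-off^2 / (2 * sigma^2))
  k <- k / sum(k)
  m <- matrix(0, n, n)
  idx <- seq_len(n)
  for (j in seq_along(off)) {
    tgt <- pmin(pmax(idx + off[j], 1L), n)
    m[cbind(idx, tgt)] <- m[cbind(idx, tgt)] + k[j]
  }
  .blur_cache[[key]] <- m
  m
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  mr <- blur1d_matrix(nrow(img), sigma)
  mc <- blur1d_matrix(ncol(img), sigma)
  mr %*% img %*% t(mc)
}

# Shift a matrix by `o` along an axis with replicate boundary.
mat_shift <- function(img, o, axis) {
  n <- dim(img)[axis]
  idx <- pmin(pmax(seq_len(n) + o, 1L), n)
  if (axis == 1L) img[idx, , drop = FALSE] else img[, idx, drop = FALSE]
}

# Separable running min/max over a (2*radius+1)^2 window.
win_extreme <- function(img, radius, fun) {
  out <- img
  for (o in setdiff(-radius:radius, 0L)) out <- fun(out, mat_shift(img, o, 1L))
  tmp <- out
  for (o in setdiff(-radius:radius, 0L)) out <- fun(out, mat_shift(tmp, o, 2L))
  out
}
win_min <- function(img, radius) win_extreme(img, radius, pmin)
win_max <- function(img, radius) win_extreme(img, radius, pmax)

# Window mean via separable box filter (replicate boundary).
box_mean <- function(img, radius) {
  w <- 2L * radius + 1L
  out <- img
  for (o in setdiff(-radius:radius, 0L)) out <- out + mat_shift(img, o, 1L)
  tmp <- out
  for (o in setdiff(-radius:radius, 0L)) out <- out + mat_shift(tmp, o, 2L)
  out / (w * w)
}

win_variance <- function(img, radius) {
  m <- box_mean(img, radius)
  m2 <- box_mean(img * img, radius)
  pmax(m2 - m * m, 0)
}

# Centroid (row, col) of TRUE pixels.
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(c(NA_real_, NA_real_))
  c(mean(idx[, 1]), mean(idx[, 2]))
}

# Apply a function over the third margin of an RGB array, returning a matrix
# list (one per channel).
split_channels <- function(image) {
  lapply(seq_len(dim(image)[3]), function(k) image[, , k])
}
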