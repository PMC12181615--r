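# Rigid-body serial-section registration: canvas standardization, pairwise
# intensity registration (multi-resolution MSE), batched alignment with two
# carried reference sections, and a reverse refinement pass.

#' Rigid transform (rotation about the canvas center, then translation)
#'
#' @param angle_deg Rotation angle in degrees.
#' @param drow,dcol Translation in pixels (rows, cols).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(angle_deg = 0, drow = 0, dcol = 0) {
  structure(
    list(angle_deg = angle_deg, drow = drow, dcol = dcol),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform: %.3f deg, shift (%.2f, %.2f) px\n",
              x$angle_deg, x$drow, x$dcol))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(t2, t1)` is the transform applying `t1` first, then
#' `t2` (both about the same canvas center).
#'
#' @param t2,t1 [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(t2, t1) {
  a2 <- t2$angle_deg * pi / 180
  r2 <- matrix(c(cos(a2), sin(a2), -sin(a2), cos(a2)), 2, 2)
  t <- r2 %*% c(t1$drow, t1$dcol) + c(t2$drow, t2$dcol)
  rigid_transform(t1$angle_deg + t2$angle_deg, t[1], t[2])
}

#' Invert a rigid transform
#' @param tf A [rigid_transform()].
#' @return A [rigid_transform()] such that composing with `tf` yields identity.
#' @export
invert_transform <- function(tf) {
  a <- -tf$angle_deg * pi / 180
  r <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  t <- -r %*% c(tf$drow, tf$dcol)
  rigid_transform(-tf$angle_deg, t[1], t[2])
}

is_label_image <- function(image) is.integer(image) || is.logical(image)

#' Apply a rigid transform to an image
#'
#' Rotation about the canvas center followed by translation; out-of-canvas
#' regions are filled with 0 (the background code). Label maps (integer or
#' logical matrices) must use nearest-neighbour interpolation so class codes
#' never blend.
#'
#' @param image Matrix (intensity or label) or RGB array.
#' @param tf A [rigid_transform()].
#' @param interpolation `"linear"` or `"nearest"`; label inputs require
#'   `"nearest"` (requesting linear is a configuration error).
#' @return Transformed image of the same type.
#' @export
apply_rigid <- function(image, tf, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (length(dim(image)) == 3L) {
    out <- image
    for (k in seq_len(dim(image)[3])) {
      out[, , k] <- cpp_warp_rigid(image[, , k], tf$angle_deg, tf$drow,
                                   tf$dcol, (interpolation == "linear") * 1L, 0)
    }
    return(out)
  }
  if (is_label_image(image) && interpolation == "linear") {
    stop_config("label masks must be transformed with nearest interpolation")
  }
  warped <- cpp_warp_rigid(
    matrix(as.numeric(image), nrow(image), ncol(image)),
    tf$angle_deg, tf$drow, tf$dcol,
    (interpolation == "linear") * 1L, 0
  )
  if (is.integer(image)) {
    matrix(as.integer(warped), nrow(warped), ncol(warped))
  } else if (is.logical(image)) {
    warped > 0
  } else {
    warped
  }
}

# --- stacks ----------------------------------------------------------------

new_stack <- function(images, pixel_size_um, transforms = NULL) {
  structure(
    list(
      images = images,
      transforms = transforms %||% replicate(length(images),
                                             rigid_transform(),
                                             simplify = FALSE),
      pixel_size_um = pixel_size_um,
      canvas = if (length(images) > 0L) dim(images[[1]])[1:2] else c(0L, 0L)
    ),
    class = "cmh_stack"
  )
}

#' @export
print.cmh_stack <- function(x, ...) {
  cat(sprintf("Section stack: %d sections, canvas %d x %d px, %.3f um/px\n",
              length(x$images), x$canvas[1], x$canvas[2], x$pixel_size_um))
  invisible(x)
}

#' Standardize section canvases
#'
#' Pads every image onto a common canvas (the max height x max width across
#' inputs), centered with `floor((canvas - size) / 2)` offsets, padding value
#' 0 (the background code). All inputs must share a pixel type.
#'
#' @param images List of matrices (all label or all intensity) or RGB arrays.
#' @param pixel_size_um Pixel calibration carried on the stack.
#' @return A `cmh_stack` with identity transforms.
#' @export
standardize_canvas <- function(images, pixel_size_um = 1.725) {
  if (length(images) < 1L) stop_data("need at least one image")
  ndims <- vapply(images, function(x) length(dim(x)), 0L)
  if (length(unique(ndims)) != 1L) {
    stop_data("mixed pixel types: cannot combine matrices and RGB arrays")
  }
  types <- vapply(images, function(x) typeof(x), "")
  if (length(unique(types)) != 1L) {
    stop_data("mixed pixel types across images")
  }
  hh <- vapply(images, function(x) dim(x)[1], 0L)
  ww <- vapply(images, function(x) dim(x)[2], 0L)
  nr <- max(hh)
  nc <- max(ww)
  rgb <- ndims[1] == 3L
  padded <- lapply(images, function(img) {
    d <- dim(img)
    ro <- (nr - d[1]) %/% 2L
    co <- (nc - d[2]) %/% 2L
    zero <- vector(typeof(img), 1L) # typed zero (0, 0L or FALSE)
    if (rgb) {
      out <- array(zero, c(nr, nc, d[3]))
      out[ro + seq_len(d[1]), co + seq_len(d[2]), ] <- img
    } else {
      out <- matrix(zero, nr, nc)
      out[ro + seq_len(d[1]), co + seq_len(d[2])] <- img
    }
    out
  })
  new_stack(padded, pixel_size_um)
}

# Block-mean downscale used for the registration pyramid.
block_mean <- function(img, f) {
  if (f == 1L) return(img)
  nr <- (nrow(img) %/% f) * f
  nc <- (ncol(img) %/% f) * f
  x <- img[seq_len(nr), seq_len(nc)]
  x <- rowsum(x, rep(seq_len(nr %/% f), each = f))
  t(rowsum(t(x), rep(seq_len(nc %/% f), each = f))) / (f * f)
}

# Single display channel for registration: labels scaled to display range,
# RGB collapsed to luma.
registration_display <- function(image) {
  if (length(dim(image)) == 3L) {
    rgb_to_yiq(image)[, , 1]
  } else if (is_label_image(image)) {
    matrix(as.numeric(image), nrow(image), ncol(image)) * 127.5
  } else {
    matrix(as.numeric(image), nrow(image), ncol(image))
  }
}

#' Register one section onto a reference
#'
#' Finds the rigid transform minimizing the mean squared intensity difference
#' between the transformed moving image and the reference, over a
#' multi-resolution pyramid (default 3 levels) with a coarse translation /
#' rotation grid initialization and Nelder-Mead refinement at every level.
#' Deterministic for fixed inputs.
#'
#' @param moving,reference Equal-size single-channel matrices (label maps are
#'   scaled to display range internally); both must be non-constant.
#' @param params Optional list: `n_levels` (3), `init_shift_px` (22),
#'   `init_step_px` (4), `init_angles_deg` (-11..11 by 2.2); the defaults
#'   cover twice the generator's per-section misalignment bounds, i.e. the
#'   worst relative displacement between consecutive sections.
#' @return The recovered [rigid_transform()] (moving -> reference), with
#'   attribute `mse` (final cost).
#' @export
register_pair <- function(moving, reference, params = list()) {
  p <- utils::modifyList(list(
    n_levels = 3L, init_shift_px = 22, init_step_px = 4,
    init_angles_deg = seq(-11, 11, by = 2.2)
  ), params)
  mov <- registration_display(moving)
  ref <- registration_display(reference)
  if (!all(dim(mov) == dim(ref))) stop_data("images must share dimensions")
  if (max(mov) == min(mov) || max(ref) == min(ref)) {
    stop_degenerate("constant image: registration undefined")
  }
  sc <- max(abs(c(mov, ref)))
  mov <- mov / sc
  ref <- ref / sc
  factors <- 2^((p$n_levels - 1L):0)
  cost <- function(par, mv, rf) {
    w <- cpp_warp_rigid(mv, par[1], par[2], par[3], 1L, 0)
    cpp_mse(w, rf)
  }
  # coarse grid init at the coarsest level (parameters in level pixels)
  f0 <- factors[1]
  mv0 <- block_mean(mov, f0)
  rf0 <- block_mean(ref, f0)
  shifts <- seq(-p$init_shift_px, p$init_shift_px, by = p$init_step_px) / f0
  best <- c(0, 0, 0)
  best_cost <- Inf
  for (a in p$init_angles_deg) {
    for (dr in shifts) {
      for (dc in shifts) {
        cc <- cost(c(a, dr, dc), mv0, rf0)
        if (cc < best_cost) {
          best_cost <- cc
          best <- c(a, dr, dc)
        }
      }
    }
  }
  par <- best # angle, drow_level, dcol_level at factor f0
  for (li in seq_along(factors)) {
    f <- factors[li]
    mv <- block_mean(mov, f)
    rf <- block_mean(ref, f)
    if (li > 1L) par[2:3] <- par[2:3] * factors[li - 1L] / f
    opt <- optim(par, cost, mv = mv, rf = rf, method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-8))
    par <- opt$par
  }
  structure(rigid_transform(par[1], par[2], par[3]), mse = opt$value)
}

#' Mean consecutive-section centroid drift
#'
#' Mean Euclidean displacement of the foreground (code > 0) centroid between
#' consecutive sections - the residual-misalignment metric used to judge
#' stack alignment.
#'
#' @param stack A `cmh_stack`.
#' @return Mean drift in pixels.
#' @export
stack_drift <- function(stack) {
  cents <- lapply(stack$images, function(img) {
    m <- if (length(dim(img)) == 3L) img[, , 1] < 250 else img > 0
    mask_centroid(m)
  })
  d <- vapply(seq_len(length(cents) - 1L), function(i) {
    sqrt(sum((cents[[i + 1L]] - cents[[i]])^2))
  }, 0)
  mean(d)
}

#' Batch grouping for reference carry-over alignment
#'
#' The first batch holds `batch_size` sections aligned independently; every
#' subsequent group prepends the last `n_refs` already-aligned sections as
#' frozen references to the next `batch_size` new sections (group size
#' `batch_size + n_refs`). A short tail is merged with the reference pair.
#'
#' @param n_sections Number of sections.
#' @param batch_size New sections per batch (default 10).
#' @param n_refs Carried references (default 2); `batch_size > n_refs >= 1`.
#' @return List of integer index vectors (references included).
#' @export
plan_batches <- function(n_sections, batch_size = 10L, n_refs = 2L) {
  if (!(batch_size > n_refs && n_refs >= 1L)) {
    stop_config("need batch_size > n_refs >= 1")
  }
  groups <- list(seq_len(min(batch_size, n_sections)))
  pos <- min(batch_size, n_sections)
  while (pos < n_sections) {
    new <- seq(pos + 1L, min(pos + batch_size, n_sections))
    refs <- seq(pos - n_refs + 1L, pos)
    groups[[length(groups) + 1L]] <- c(refs, new)
    pos <- max(new)
  }
  groups
}

#' Batched rigid alignment of a section stack
#'
#' Aligns each section to its already-aligned predecessor, processing the
#' stack in batches with `n_refs` reference sections carried over from the
#' previous batch; references are frozen (never re-transformed) so alignment
#' stays consistent across batch boundaries. Cumulative transforms are
#' recorded per section.
#'
#' @param stack A `cmh_stack` (label maps or intensity images).
#' @param batch_size New sections per batch (default 10).
#' @param n_refs Carried references (default 2).
#' @param register_params Passed to [register_pair()].
#' @return The aligned `cmh_stack`; `$transforms` holds per-section cumulative
#'   transforms and attribute `groups` the batch plan.
#' @export
align_batched <- function(stack, batch_size = 10L, n_refs = 2L,
                          register_params = list()) {
  stopifnot(inherits(stack, "cmh_stack"))
  n <- length(stack$images)
  groups <- plan_batches(n, batch_size, n_refs)
  aligned <- stack$images
  tfs <- replicate(n, rigid_transform(), simplify = FALSE)
  done <- rep(FALSE, n)
  done[1] <- TRUE
  for (g in groups) {
    for (i in g) {
      if (done[i]) next # reference sections are frozen
      tf <- register_pair(aligned[[i]], aligned[[i - 1L]], register_params)
      aligned[[i]] <- apply_rigid(
        stack$images[[i]], tf,
        interpolation = if (is_label_image(stack$images[[i]])) "nearest" else "linear"
      )
      tfs[[i]] <- compose_transforms(tf, stack$transforms[[i]])
      done[i] <- TRUE
    }
  }
  out <- new_stack(aligned, stack$pixel_size_um, tfs)
  attr(out, "groups") <- groups
  out
}

#' Reverse-pass alignment refinement
#'
#' Re-runs batched alignment on the reversed stack and restores the original
#' order; keeps the refined stack only if it does not increase the mean
#' centroid drift, so the pass can only hold or improve residual alignment.
#'
#' @inheritParams align_batched
#' @return The refined `cmh_stack`, with attribute `drift` holding
#'   `c(before, after)`.
#' @export
reverse_pass_align <- function(stack, batch_size = 10L, n_refs = 2L,
                               register_params = list()) {
  stopifnot(inherits(stack, "cmh_stack"))
  d0 <- stack_drift(stack)
  n <- length(stack$images)
  rev_stack <- new_stack(rev(stack$images), stack$pixel_size_um,
                         rev(stack$transforms))
  refined <- align_batched(rev_stack, batch_size, n_refs, register_params)
  restored <- new_stack(rev(refined$images), stack$pixel_size_um,
                        rev(refined$transforms))
  d1 <- stack_drift(restored)
  out <- if (d1 <= d0) restored else stack
  attr(out, "drift") <- c(before = d0, after = stack_drift(out))
  out
}

#' Write a stack's transforms as CSV
#' @param stack A `cmh_stack`.
#' @param path Output CSV (section, angle_deg, drow, dcol).
#' @return Invisibly, `path`.
#' @export
write_transforms_csv <- function(stack, path) {
  df <- data.frame(
    section = seq_along(stack$transforms),
    angle_deg = vapply(stack$transforms, `[[`, 0, "angle_deg"),
    drow = vapply(stack$transforms, `[[`, 0, "drow"),
    dcol = vapply(stack$transforms, `[[`, 0, "dcol")
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
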