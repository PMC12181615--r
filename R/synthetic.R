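# Synthetic hematoxylin/DAB slide generator with exact ground truth.
#
# Sections are rendered through the same Beer-Lambert HDAB forward model the
# deconvolution stage inverts, so stain unmixing is exactly invertible in the
# noise-free limit. One smooth 3D tissue silhouette is shared by all sections
# of a stack and sampled along the rostro-caudal axis; each section is
# independently perturbed by a bounded random rigid transform whose true
# parameters are recorded.

#' Configuration for the synthetic slide generator
#'
#' Defaults emulate the imaging material of the study the pipeline was built
#' for: whole coronal mouse sections scanned at 40x and downscaled to 20%
#' (assumed 1.725 um/px; the scan resolution is configurable because it is an
#' assumption, not a measured value), ~30 microbleeds per brain in a 2:1
#' small(<50 um):large(>100 um) mix, dark debris artifacts near the tissue
#' boundary, mild staining jitter, and small random inter-section rigid
#' misalignments.
#'
#' @param image_size_px Canvas size `c(rows, cols)`.
#' @param pixel_size_um Pixel calibration in micrometers per pixel (> 0).
#' @param n_sections Number of serial sections (>= 1).
#' @param tissue_shape_seed Seed controlling the 3D silhouette shape.
#' @param n_bleeds_total Total planted microbleeds across the stack (>= 0).
#' @param bleed_diameter_range_um Diameter range `c(min, max)`; must straddle
#'   the small/large training classes (min < 50, max > 100) whenever both
#'   classes are requested.
#' @param small_large_mix Fraction of bleeds with diameter < 50 um
#'   (default 2/3, i.e. 20 small : 10 large at the default count).
#' @param artifact_rate Expected dark-debris artifacts per section (>= 0).
#' @param stain_intensity_jitter Coefficient of variation of per-section and
#'   per-object stain intensity (>= 0).
#' @param misalignment_translation_px Max absolute per-axis translation.
#' @param misalignment_rotation_deg Max absolute rotation in degrees.
#' @param noise_sd Gaussian sensor noise SD in digital numbers, added after
#'   staining synthesis; ground truth is pre-noise.
#' @param min_bleed_separation_px Minimum gap between planted bleeds so
#'   objects stay resolvable after factor-5 downscaling.
#' @param rng_seed Master seed; identical configs generate byte-identical
#'   stacks.
#' @return An object of class `slide_sim_config` (a validated list).
#' @export
slide_sim_config <- function(image_size_px = c(420L, 560L),
                             pixel_size_um = 1.725,
                             n_sections = 40L,
                             tissue_shape_seed = 11L,
                             n_bleeds_total = 30L,
                             bleed_diameter_range_um = c(15, 150),
                             small_large_mix = 2 / 3,
                             artifact_rate = 2,
                             stain_intensity_jitter = 0.1,
                             misalignment_translation_px = 10,
                             misalignment_rotation_deg = 5,
                             noise_sd = 2,
                             min_bleed_separation_px = 12,
                             rng_seed = 1L) {
  cfg <- list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um,
    n_sections = as.integer(n_sections),
    tissue_shape_seed = as.integer(tissue_shape_seed),
    n_bleeds_total = as.integer(n_bleeds_total),
    bleed_diameter_range_um = as.numeric(bleed_diameter_range_um),
    small_large_mix = small_large_mix,
    artifact_rate = artifact_rate,
    stain_intensity_jitter = stain_intensity_jitter,
    misalignment_translation_px = misalignment_translation_px,
    misalignment_rotation_deg = misalignment_rotation_deg,
    noise_sd = noise_sd,
    min_bleed_separation_px = min_bleed_separation_px,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "slide_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!ok) stop_config(sprintf("invalid %s: %s", field, what))
  }
  chk(length(cfg$image_size_px) == 2L && all(cfg$image_size_px >= 32L),
      "image_size_px", "need c(rows, cols) with both >= 32")
  chk(is.numeric(cfg$pixel_size_um) && cfg$pixel_size_um > 0,
      "pixel_size_um", "must be > 0")
  chk(cfg$n_sections >= 1L, "n_sections", "must be >= 1")
  chk(cfg$n_bleeds_total >= 0L, "n_bleeds_total", "must be >= 0")
  rng <- cfg$bleed_diameter_range_um
  chk(length(rng) == 2L && rng[1] > 0 && rng[2] > rng[1],
      "bleed_diameter_range_um", "need 0 < min < max")
  chk(cfg$small_large_mix >= 0 && cfg$small_large_mix <= 1,
      "small_large_mix", "must be in [0, 1]")
  n_small <- round(cfg$small_large_mix * cfg$n_bleeds_total)
  if (n_small > 0) {
    chk(rng[1] < 50, "bleed_diameter_range_um",
        "min must be < 50 um to allow small-class bleeds")
  }
  if (cfg$n_bleeds_total - n_small > 0) {
    chk(rng[2] > 100, "bleed_diameter_range_um",
        "max must be > 100 um to allow large-class bleeds")
  }
  chk(cfg$artifact_rate >= 0, "artifact_rate", "must be >= 0")
  chk(cfg$stain_intensity_jitter >= 0, "stain_intensity_jitter", "must be >= 0")
  chk(cfg$misalignment_translation_px >= 0, "misalignment_translation_px",
      "must be >= 0")
  chk(cfg$misalignment_rotation_deg >= 0, "misalignment_rotation_deg",
      "must be >= 0")
  chk(cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(cfg$rng_seed == cfg$rng_seed %% 2147483647, "rng_seed",
      "must be a 32-bit integer")
  cfg
}

# --- deterministic stack plan ----------------------------------------------
# Everything drawn here depends only on the config, never on which section is
# generated first, so generate_section(i) and generate_stack() agree.

stack_plan <- function(cfg) {
  shape <- with_seed(derive_seed(cfg$tissue_shape_seed, 1L), {
    list(
      # fixed dorsoventral asymmetry (k = 1): breaks the near-elliptical
      # rotational ambiguity the way a real coronal profile does; constant
      # along z so it offsets all section centroids equally
      a1 = runif(1, 0.08, 0.12),
      phase1 = runif(1, 0, 2 * pi),
      amp = runif(3, 0.02, 0.06),          # harmonics k = 2..4
      freq = runif(3, 0.3, 0.8),
      phase = runif(3, 0, 2 * pi),
      zphase = runif(3, 0, 1),
      hole_off = c(runif(1, -0.06, 0.06), runif(1, -0.06, 0.06)),
      hole_ax = c(runif(1, 0.05, 0.08), runif(1, 0.04, 0.07))
    )
  })
  n <- cfg$n_sections
  per_section <- with_seed(derive_seed(cfg$rng_seed, 2L), {
    list(
      angle = runif(n, -1, 1) * cfg$misalignment_rotation_deg,
      drow = runif(n, -1, 1) * cfg$misalignment_translation_px,
      dcol = runif(n, -1, 1) * cfg$misalignment_translation_px,
      h_jit = rlnorm(n, -cfg$stain_intensity_jitter^2 / 2,
                     cfg$stain_intensity_jitter),
      n_artifacts = rpois(n, cfg$artifact_rate)
    )
  })
  bleeds <- with_seed(derive_seed(cfg$rng_seed, 3L), {
    nb <- cfg$n_bleeds_total
    if (nb == 0L) {
      data.frame(
        id = integer(), section = integer(), diameter_um = numeric(),
        ecc = numeric(), angle = numeric(), dab_jit = numeric()
      )
    } else {
      n_small <- round(cfg$small_large_mix * nb)
      rngd <- cfg$bleed_diameter_range_um
      d <- c(
        if (n_small > 0) runif(n_small, rngd[1], min(49.5, rngd[2])),
        if (nb - n_small > 0) runif(nb - n_small, max(100.5, rngd[1]), rngd[2])
      )
      data.frame(
        id = seq_len(nb),
        section = sample.int(cfg$n_sections, nb, replace = TRUE),
        diameter_um = d,
        ecc = runif(nb, 1, 1.3),
        angle = runif(nb, 0, pi),
        dab_jit = rlnorm(nb, -cfg$stain_intensity_jitter^2 / 2,
                         cfg$stain_intensity_jitter)
      )
    }
  })
  list(shape = shape, per_section = per_section, bleeds = bleeds)
}

# Silhouette parameters at normalized depth z in [0, 1]. One z unit is the
# full rostro-caudal extent (~10 mm); retained sections are 20 um apart
# (8 um thickness, 2-of-5 retention), so consecutive sections advance by
# 0.002 z units around the mid-brain - the slow per-section shape change of
# real serial histology.
section_geometry <- function(cfg, section_index, shape) {
  z <- 0.5 + (section_index - (cfg$n_sections + 1) / 2) * 0.002
  f <- 0.55 + 0.45 * sqrt(pmax(1 - (2 * z - 1)^2, 0))
  amp <- shape$amp * cos(2 * pi * (shape$freq * z + shape$zphase))
  hole_scale <- pmin(pmax(1.2 * sin(pi * z), 0.3), 1)
  list(z = z, f = f, a1 = shape$a1, phase1 = shape$phase1,
       amp = amp, phase = shape$phase,
       hole_off = shape$hole_off, hole_ax = shape$hole_ax * hole_scale)
}

# Canonical (pre-misalignment) coordinates of the observed pixel grid under
# the section's rigid transform (rotation about canvas center, then shift).
canonical_coords <- function(nr, nc, tf) {
  cr <- (nr + 1) / 2
  cc <- (nc + 1) / 2
  r <- matrix(seq_len(nr), nr, nc) - tf$drow - cr
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - tf$dcol - cc
  a <- -tf$angle_deg * pi / 180
  list(r = cos(a) * r - sin(a) * c + cr, c = sin(a) * r + cos(a) * c + cc)
}

# Tissue / ventricle masks evaluated on canonical coordinates.
silhouette_masks <- function(cfg, geom, coords) {
  nr <- cfg$image_size_px[1]
  nc <- cfg$image_size_px[2]
  ar <- 0.36 * nr
  ac <- 0.38 * nc
  cr <- (nr + 1) / 2
  cc <- (nc + 1) / 2
  rn <- (coords$r - cr) / ar
  cn <- (coords$c - cc) / ac
  u <- sqrt(rn^2 + cn^2)
  th <- atan2(cn, rn)
  b <- geom$f * (1 +
    geom$a1 * cos(th + geom$phase1) +
    geom$amp[1] * cos(2 * th + geom$phase[1]) +
    geom$amp[2] * cos(3 * th + geom$phase[2]) +
    geom$amp[3] * cos(4 * th + geom$phase[3]))
  outer_mask <- u <= b
  hr <- (coords$r - (cr + geom$hole_off[1] * nr)) / (geom$hole_ax[1] * nr)
  hc <- (coords$c - (cc + geom$hole_off[2] * nc)) / (geom$hole_ax[2] * nc)
  hole <- (hr^2 + hc^2) <= 1
  list(tissue = outer_mask & !hole, hole = hole & outer_mask)
}

# Elliptical object rasterizer: returns mask and feathered stain coverage on
# a local window. q is the normalized elliptical radius; the ground-truth
# boundary sits at q = 1, where rendered coverage is 0.5.
raster_ellipse <- function(nr, nc, center, semi, angle, feather = 0.08) {
  rad <- ceiling(max(semi)) + 2L
  r0 <- max(1L, floor(center[1] - rad))
  r1 <- min(nr, ceiling(center[1] + rad))
  c0 <- max(1L, floor(center[2] - rad))
  c1 <- min(nc, ceiling(center[2] + rad))
  if (r0 > r1 || c0 > c1) return(NULL)
  rr <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L) - center[1]
  cc <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE) - center[2]
  x1 <- cos(angle) * rr + sin(angle) * cc
  x2 <- -sin(angle) * rr + cos(angle) * cc
  q <- sqrt((x1 / semi[1])^2 + (x2 / semi[2])^2)
  list(
    rows = r0:r1, cols = c0:c1,
    mask = q <= 1,
    coverage = pmin(pmax((1 + feather - q) / (2 * feather), 0), 1)
  )
}

# Smooth multiplicative texture for the hematoxylin field.
smooth_field <- function(nr, nc, seed, coarse = c(15L, 20L), amp = 0.12) {
  g <- with_seed(seed, matrix(rnorm(prod(coarse)), coarse[1], coarse[2]))
  ri <- seq(1, coarse[1], length.out = nr)
  ci <- seq(1, coarse[2], length.out = nc)
  r0 <- pmin(floor(ri), coarse[1] - 1L)
  c0 <- pmin(floor(ci), coarse[2] - 1L)
  fr <- ri - r0
  fc <- ci - c0
  m00 <- g[r0, c0, drop = FALSE]
  m01 <- g[r0, c0 + 1L, drop = FALSE]
  m10 <- g[r0 + 1L, c0, drop = FALSE]
  m11 <- g[r0 + 1L, c0 + 1L, drop = FALSE]
  FR <- matrix(fr, nr, nc)
  FC <- matrix(fc, nr, nc, byrow = TRUE)
  up <- (1 - FR) * (1 - FC) * m00 + (1 - FR) * FC * m01 +
    FR * (1 - FC) * m10 + FR * FC * m11
  1 + amp * up / max(abs(up), 1e-9)
}

#' Generate one synthetic stained section
#'
#' Renders an 8-bit RGB brightfield image of a hematoxylin-stained tissue
#' silhouette (with an interior ventricle hole) carrying DAB-stained
#' elliptical microbleeds, via Beer-Lambert mixing with the shared HDAB stain
#' matrix, on a white background. Dark achromatic debris artifacts are added
#' near the tissue boundary at the configured rate, the whole scene is
#' displaced by the section's true rigid misalignment, and Gaussian sensor
#' noise is added last. Ground-truth masks are pixel-exact and pre-noise.
#'
#' @param config A [slide_sim_config()].
#' @param section_index Section number in `1..n_sections`.
#' @return List with elements `image` (rows x cols x 3 array, 0-255) and
#'   `truth`: `tissue` (logical matrix), `bleeds` (integer label matrix with
#'   per-object ids), `artifacts` (logical matrix), `transform` (the true
#'   [rigid_transform()]), and `objects` (data frame: id, section, row_px,
#'   col_px, diameter_um, area_um2).
#' @export
generate_section <- function(config, section_index) {
  stopifnot(inherits(config, "slide_sim_config"))
  validate_sim_config(config)
  if (section_index < 1L || section_index > config$n_sections) {
    stop_config("invalid section_index: must be in 1..n_sections")
  }
  plan <- stack_plan(config)
  generate_section_impl(config, section_index, plan)
}

generate_section_impl <- function(cfg, i, plan) {
  nr <- cfg$image_size_px[1]
  nc <- cfg$image_size_px[2]
  ps <- plan$per_section
  tf <- rigid_transform(ps$angle[i], ps$drow[i], ps$dcol[i])
  geom <- section_geometry(cfg, i, plan$shape)
  coords <- canonical_coords(nr, nc, tf)
  masks <- silhouette_masks(cfg, geom, coords)
  tissue <- masks$tissue

  # --- plant bleeds (observed grid; placement seeded per section) ----------
  specs <- plan$bleeds[plan$bleeds$section == i, , drop = FALSE]
  # place the largest objects first so late draws still find room
  specs <- specs[order(-specs$diameter_um), , drop = FALSE]
  bleed_lab <- matrix(0L, nr, nc)
  dab <- matrix(0, nr, nc)
  objects <- data.frame(
    id = integer(), section = integer(), row_px = numeric(),
    col_px = numeric(), diameter_um = numeric(), area_um2 = numeric()
  )
  placed <- list()
  if (nrow(specs) > 0L) {
    tissue_idx <- which(tissue)
    if (length(tissue_idx) == 0L) stop_data("tissue silhouette is empty")
    with_seed(derive_seed(cfg$rng_seed, 4L, i), {
      for (j in seq_len(nrow(specs))) {
        sp <- specs[j, ]
        semi <- c(sp$diameter_um / 2 * sp$ecc,
                  sp$diameter_um / 2 / sp$ecc) / cfg$pixel_size_um
        ok <- FALSE
        for (try in 1:2000) {
          pick <- tissue_idx[sample.int(length(tissue_idx), 1L)]
          ctr <- c((pick - 1L) %% nr + 1L, (pick - 1L) %/% nr + 1L) +
            runif(2, -0.5, 0.5)
          re <- raster_ellipse(nr, nc, ctr, semi, sp$angle)
          if (is.null(re)) next
          sub <- tissue[re$rows, re$cols, drop = FALSE]
          if (!all(sub[re$mask])) next
          sep_ok <- TRUE
          for (p in placed) {
            if (sqrt(sum((ctr - p$ctr)^2)) <=
                max(semi) + p$rmax + cfg$min_bleed_separation_px) {
              sep_ok <- FALSE
              break
            }
          }
          if (!sep_ok) next
          blk <- bleed_lab[re$rows, re$cols, drop = FALSE]
          blk[re$mask] <- sp$id
          bleed_lab[re$rows, re$cols] <- blk
          dsub <- dab[re$rows, re$cols, drop = FALSE]
          dab[re$rows, re$cols] <- pmax(dsub, 0.9 * sp$dab_jit * re$coverage)
          placed[[length(placed) + 1L]] <- list(ctr = ctr, rmax = max(semi))
          npx <- sum(re$mask)
          objects <- rbind(objects, data.frame(
            id = sp$id, section = i, row_px = ctr[1], col_px = ctr[2],
            diameter_um = sp$diameter_um,
            area_um2 = npx * cfg$pixel_size_um^2
          ))
          ok <- TRUE
          break
        }
        if (!ok) {
          stop_data(sprintf(
            "could not place bleed %d on section %d: tissue too crowded",
            sp$id, i
          ))
        }
      }
    })
  }

  # --- hematoxylin concentration field -------------------------------------
  tex <- smooth_field(nr, nc, derive_seed(cfg$rng_seed, 5L, i))
  hconc <- matrix(0, nr, nc)
  hconc[tissue] <- 0.55 * ps$h_jit[i] * tex[tissue]

  conc <- array(0, c(nr, nc, 3L))
  conc[, , 1] <- hconc
  conc[, , 2] <- dab
  img <- reconstruct_rgb(conc, hdab_stain_matrix(), quantize = TRUE)

  # --- achromatic debris artifacts near the tissue boundary ----------------
  artifacts <- matrix(FALSE, nr, nc)
  if (ps$n_artifacts[i] > 0L) {
    edge <- tissue & !win_min(tissue, 1L)
    edge_idx <- which(edge)
    if (length(edge_idx) > 0L) {
      with_seed(derive_seed(cfg$rng_seed, 6L, i), {
        for (k in seq_len(ps$n_artifacts[i])) {
          for (try in 1:100) {
            pick <- edge_idx[sample.int(length(edge_idx), 1L)]
            ctr <- c((pick - 1L) %% nr + 1L, (pick - 1L) %/% nr + 1L) +
              runif(2, -6, 6)
            d <- runif(1, 3, 8)
            re <- raster_ellipse(nr, nc, ctr, c(d / 2, d / 2 / runif(1, 1, 1.3)),
                                 runif(1, 0, pi), feather = 0.2)
            if (is.null(re)) next
            hit <- bleed_lab[re$rows, re$cols, drop = FALSE]
            if (any(hit[re$mask] > 0L)) next
            v <- runif(1, 4, 18)
            sub <- artifacts[re$rows, re$cols, drop = FALSE]
            sub[re$mask] <- TRUE
            artifacts[re$rows, re$cols] <- sub
            for (ch in 1:3) {
              chsub <- img[re$rows, re$cols, ch]
              chsub[re$mask] <- pmin(pmax(round(
                v + runif(sum(re$mask), -2, 2)
              ), 0), 255)
              img[re$rows, re$cols, ch] <- chsub
            }
            break
          }
        }
      })
    }
  }

  # --- sensor noise (ground truth is pre-noise) ----------------------------
  if (cfg$noise_sd > 0) {
    noise <- with_seed(
      derive_seed(cfg$rng_seed, 7L, i),
      array(rnorm(length(img), 0, cfg$noise_sd), dim(img))
    )
    img <- pmin(pmax(round(img + noise), 0), 255)
  }

  list(
    image = img,
    truth = list(
      tissue = tissue, bleeds = bleed_lab, artifacts = artifacts,
      transform = tf, objects = objects
    )
  )
}

#' Generate a serial stack of synthetic sections
#'
#' All sections share one underlying 3D tissue silhouette sampled along the
#' rostro-caudal axis; each is perturbed by its own bounded random rigid
#' transform. The combined ground truth stands in for expert manual counts
#' when benchmarking segmentation methods.
#'
#' @param config A [slide_sim_config()].
#' @return List of class `cmh_synthetic_stack` with `images` (list of RGB
#'   arrays), `truth` (per-section truth lists as in [generate_section()]),
#'   `objects` (combined ground-truth object table), `transforms` (true rigid
#'   transforms) and `config`.
#' @export
generate_stack <- function(config) {
  stopifnot(inherits(config, "slide_sim_config"))
  validate_sim_config(config)
  plan <- stack_plan(config)
  secs <- lapply(seq_len(config$n_sections), function(i) {
    generate_section_impl(config, i, plan)
  })
  out <- list(
    images = lapply(secs, `[[`, "image"),
    truth = lapply(secs, `[[`, "truth"),
    objects = do.call(rbind, lapply(secs, function(s) s$truth$objects)),
    transforms = lapply(secs, function(s) s$truth$transform),
    config = config
  )
  class(out) <- "cmh_synthetic_stack"
  out
}

#' @export
print.cmh_synthetic_stack <- function(x, ...) {
  cat(sprintf(
    "Synthetic CMH stack: %d sections (%d x %d px, %.3f um/px), %d bleeds\n",
    length(x$images), x$config$image_size_px[1], x$config$image_size_px[2],
    x$config$pixel_size_um, nrow(x$objects)
  ))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Sections as 8-bit RGB TIFF (`sec_0001.tif`, ...), ground-truth bleed label
#' maps as 16-bit TIFF, the object table as CSV and the configuration as
#' YAML.
#'
#' @param stack Result of [generate_stack()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_synthetic_dataset <- function(stack, dir) {
  stopifnot(inherits(stack, "cmh_synthetic_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(stack$images)) {
    tiff::writeTIFF(
      stack$images[[i]] / 255,
      file.path(dir, sprintf("sec_%04d.tif", i))
    )
    tiff::writeTIFF(
      stack$truth[[i]]$bleeds / 65535,
      file.path(dir, sprintf("truth_%04d.tif", i)),
      bits.per.sample = 16L
    )
  }
  obj <- stack$objects
  write.csv(
    data.frame(
      id = obj$id, section = obj$section, x_px = obj$col_px,
      y_px = obj$row_px, diameter_um = obj$diameter_um,
      area_um2 = obj$area_um2
    ),
    file.path(dir, "ground_truth_objects.csv"),
    row.names = FALSE
  )
  cfg <- unclass(stack$config)
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
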