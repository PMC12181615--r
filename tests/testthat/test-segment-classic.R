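# Classic segmentation: Otsu, bandpass, binarize, hole filling, particle
# analysis, and the HDAB / YIQ method pipelines.

test_that("Otsu threshold equals the exhaustive maximizer", {
  # clean two-value image
  v <- c(rep(50, 60), rep(200, 40))
  t1 <- otsu_threshold(v)
  expect_true(t1 > 50 && t1 <= 200)
  expect_equal(sum(v <= t1), 60)

  expect_equal(otsu_threshold(c(0, 0, 255)), otsu_bruteforce(c(0, 0, 255)))

  withr::with_seed(11, {
    for (k in 1:25) {
      v <- switch(1 + k %% 5,
        rnorm(300, 100, 20),
        c(rnorm(150, 60, 5), rnorm(150, 180, 5)),
        sample(c(0, 1, 254, 255), 100, replace = TRUE),
        runif(200, -40, 40),                         # signed floats
        rep(c(10, 11, 200), times = c(5, 5, 290))    # tie-prone histogram
      )
      if (max(v) == min(v)) next
      expect_equal(otsu_threshold(v), otsu_bruteforce(v),
                   info = sprintf("case %d", k))
    }
  })
  expect_error(otsu_threshold(rep(5, 10)), class = "cmhq_degenerate_error")
})

test_that("bandpass suppresses both very small and very large structures", {
  flat <- matrix(42, 40, 40)
  out <- bandpass_filter(flat, 50, 2)
  expect_equal(out, flat)

  # impulse (width 1) vs width-10 blob under small_size = 2
  img <- matrix(0, 120, 240)
  img[60, 60] <- 100
  rr <- matrix(seq_len(120), 120, 240)
  cc <- matrix(seq_len(240), 120, 240, byrow = TRUE)
  img[(rr - 60)^2 + (cc - 180)^2 <= 25] <- 100
  f <- bandpass_filter(img, 50, 2)
  base <- median(f)
  impulse_peak <- max(f[55:65, 55:65]) - base
  blob_peak <- max(f[55:65, 175:185]) - base
  expect_lt(impulse_peak, 0.5 * blob_peak)

  # interior of a diameter-200 blob is flattened relative to a diameter-20
  # blob under large_size = 50 (edges are retained by design)
  img2 <- matrix(0, 260, 520)
  rr <- matrix(seq_len(260), 260, 520)
  cc <- matrix(seq_len(520), 260, 520, byrow = TRUE)
  img2[(rr - 130)^2 + (cc - 130)^2 <= 100^2] <- 100
  img2[(rr - 130)^2 + (cc - 390)^2 <= 10^2] <- 100
  f2 <- bandpass_filter(img2, 50, 2)
  base2 <- median(f2)
  big_interior <- max(f2[105:155, 105:155]) - base2 # central 50 px core
  small_peak <- max(f2[120:140, 380:400]) - base2
  expect_lt(big_interior, 0.2 * small_peak)

  expect_error(bandpass_filter(flat, 2, 2), class = "cmhq_config_error")
})

test_that("binarize respects polarity and thresholds complement", {
  img <- matrix(c(1, 5, 9, 5), 2, 2)
  expect_false(any(binarize(img, 10, "bright")))
  expect_true(all(binarize(img, 0, "bright")))
  t <- 5
  expect_equal(binarize(img, t, "bright") | binarize(img, t, "dark") |
                 (img == t), matrix(TRUE, 2, 2))
  expect_false(any(binarize(img, t, "bright") & binarize(img, t, "dark")))
})

test_that("fill_holes fills enclosed background only", {
  ring <- matrix(FALSE, 5, 5)
  ring[2:4, 2:4] <- TRUE
  ring[3, 3] <- FALSE
  filled <- fill_holes(ring)
  expect_true(filled[3, 3])
  expect_equal(sum(filled), 9)

  open <- matrix(FALSE, 4, 4)
  open[2, 2:3] <- TRUE
  expect_equal(fill_holes(open), open)

  withr::with_seed(21, {
    for (k in 1:20) {
      m <- matrix(runif(15 * 17) < 0.45, 15, 17)
      got <- fill_holes(m)
      expect_equal(got, fill_holes_oracle(m))
      expect_true(all(got[m])) # foreground never removed
    }
  })
})

test_that("particle analysis matches a flood-fill oracle at both connectivities", {
  empty <- analyze_particles(matrix(FALSE, 5, 5), 1)
  expect_equal(nrow(empty), 0L)

  diag2 <- matrix(FALSE, 4, 4)
  diag2[2, 2] <- diag2[3, 3] <- TRUE
  expect_equal(nrow(analyze_particles(diag2, 1, min_area_um2 = 0,
                                      connectivity = 8L)), 1L)
  expect_equal(nrow(analyze_particles(diag2, 1, min_area_um2 = 0,
                                      connectivity = 4L)), 2L)

  withr::with_seed(31, {
    for (k in 1:20) {
      m <- matrix(runif(20 * 24) < 0.4, 20, 24)
      for (conn in c(4L, 8L)) {
        p <- analyze_particles(m, 2, min_area_um2 = 0, connectivity = conn)
        oracle <- flood_fill_label(m, conn)
        expect_equal(nrow(p), max(oracle))
        expect_equal(sort(p$pixels), sort(as.integer(tabulate(oracle[oracle > 0]))))
        expect_equal(p$area_um2, p$pixels * 4)
      }
    }
  })

  # conservation: kept pixels + dropped pixels = foreground
  withr::with_seed(32, m <- matrix(runif(30 * 30) < 0.3, 30, 30))
  p <- analyze_particles(m, 1, min_area_um2 = 4)
  expect_equal(sum(p$pixels) + attr(p, "dropped_pixels"), sum(m))
})

test_that("both methods find every planted bleed on clean sections", {
  cfg <- slide_sim_config(
    image_size_px = c(300, 400), n_sections = 1L, n_bleeds_total = 6L,
    artifact_rate = 0, noise_sd = 0, misalignment_translation_px = 0,
    misalignment_rotation_deg = 0, rng_seed = 61L
  )
  sec <- generate_section(cfg, 1)
  for (method in c("yiq", "hdab")) {
    mask <- if (method == "yiq") segment_yiq(sec$image) else segment_hdab(sec$image)
    mo <- match_objects(sec$truth$bleeds, mask)
    expect_equal(mean(mo$detected), 1, info = method) # recall
    p <- analyze_particles(mask, cfg$pixel_size_um)
    expect_equal(nrow(p), 6L, info = method)          # precision
  }
})

test_that("artifact-rich sections over-count under HDAB but not YIQ", {
  cfg <- slide_sim_config(
    image_size_px = c(300, 400), n_sections = 2L, n_bleeds_total = 4L,
    artifact_rate = 6, rng_seed = 62L
  )
  st <- generate_stack(cfg)
  n_truth <- n_hdab <- n_yiq <- 0
  for (i in 1:2) {
    n_truth <- n_truth + sum(st$objects$section == i)
    n_hdab <- n_hdab +
      nrow(analyze_particles(segment_hdab(st$images[[i]]), cfg$pixel_size_um))
    n_yiq <- n_yiq +
      nrow(analyze_particles(segment_yiq(st$images[[i]]), cfg$pixel_size_um))
  }
  expect_gt(n_hdab, n_truth)
  expect_lt(abs(n_yiq / n_truth - 1), abs(n_hdab / n_truth - 1))
})

test_that("degenerate inputs are handled as documented", {
  blank <- array(255, c(40, 40, 3))
  m <- segment_hdab(blank)
  expect_false(any(m))

  # bleed-free tissue: near-empty YIQ mask
  cfg <- tiny_sim(n_bleeds_total = 0L, noise_sd = 2)
  sec <- generate_section(cfg, 1)
  m2 <- segment_yiq(sec$image)
  expect_lt(sum(m2), 0.001 * sum(sec$truth$tissue))

  # achromatic image: I channel constant -> degenerate error from Otsu
  gray <- array(rep(seq(40, 200, length.out = 50), 150), c(50, 50, 3))
  expect_error(segment_yiq(gray), class = "cmhq_degenerate_error")
})

test_that("segmentation is deterministic and masks serialize as 0/255", {
  cfg <- tiny_sim(n_bleeds_total = 2L, noise_sd = 2, artifact_rate = 1)
  sec <- generate_section(cfg, 1)
  expect_identical(unclass(segment_yiq(sec$image)),
                   unclass(segment_yiq(sec$image)),
                   ignore_attr = TRUE)
  expect_identical(unclass(segment_hdab(sec$image)),
                   unclass(segment_hdab(sec$image)),
                   ignore_attr = TRUE)
  path <- withr::local_tempfile(fileext = ".tif")
  write_mask_tiff(segment_yiq(sec$image), path)
  back <- tiff::readTIFF(path)
  expect_true(all(back %in% c(0, 1)))
  expect_true(file.exists(paste0(path, ".json")))
})
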