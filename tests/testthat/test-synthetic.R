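# Synthetic slide generator: validation, determinism, containment, scale.

test_that("configuration errors name the offending field", {
  expect_error(slide_sim_config(pixel_size_um = -1), "pixel_size_um",
               class = "cmhq_config_error")
  expect_error(slide_sim_config(n_sections = 0), "n_sections",
               class = "cmhq_config_error")
  expect_error(slide_sim_config(bleed_diameter_range_um = c(60, 150)),
               "bleed_diameter_range_um", class = "cmhq_config_error")
  expect_error(slide_sim_config(bleed_diameter_range_um = c(15, 90)),
               "bleed_diameter_range_um", class = "cmhq_config_error")
  expect_error(generate_section(tiny_sim(), 99), class = "cmhq_config_error")
})

test_that("bleed-free sections contain only bluish tissue on white", {
  cfg <- tiny_sim(n_bleeds_total = 0L)
  sec <- generate_section(cfg, 1)
  expect_equal(sum(sec$truth$bleeds), 0)
  expect_equal(nrow(sec$truth$objects), 0L)
  tissue <- sec$truth$tissue
  bg <- !tissue
  # white background
  expect_true(all(sec$image[, , 1][bg] == 255))
  # hematoxylin tissue is blue-dominant (B > R > ...) and darker than bg
  expect_gt(mean(sec$image[, , 3][tissue]), mean(sec$image[, , 1][tissue]))
  expect_lt(mean(sec$image[, , 1][tissue]), 200)
})

test_that("planting is count-exact and the size mix follows the 2:1 recipe", {
  cfg <- slide_sim_config(
    image_size_px = c(420, 560), n_sections = 1L, n_bleeds_total = 20L,
    bleed_diameter_range_um = c(15, 110), artifact_rate = 0, noise_sd = 0,
    rng_seed = 5L
  )
  sec <- generate_section(cfg, 1)
  expect_equal(nrow(sec$truth$objects), 20L)
  expect_equal(length(unique(sec$truth$bleeds[sec$truth$bleeds > 0])), 20L)

  cfg2 <- slide_sim_config(n_sections = 12L, n_bleeds_total = 30L,
                           small_large_mix = 2 / 3, rng_seed = 8L)
  st <- generate_stack(cfg2)
  expect_equal(nrow(st$objects), 30L)
  expect_equal(sum(st$objects$diameter_um < 50), 20L)
  expect_equal(sum(st$objects$diameter_um > 100), 10L)
})

test_that("identical configs generate byte-identical stacks", {
  cfg <- tiny_sim(artifact_rate = 1, noise_sd = 2,
                  misalignment_translation_px = 5,
                  misalignment_rotation_deg = 3)
  a <- generate_stack(cfg)
  b <- generate_stack(cfg)
  expect_identical(a$images, b$images)
  expect_identical(a$objects, b$objects)
  # stack and single-section paths agree
  sec2 <- generate_section(cfg, 2)
  expect_identical(sec2$image, a$images[[2]])
})

test_that("bleeds stay inside tissue and artifacts avoid bleeds", {
  cfg <- slide_sim_config(n_sections = 6L, n_bleeds_total = 18L,
                          artifact_rate = 3, rng_seed = 12L)
  st <- generate_stack(cfg)
  for (tr in st$truth) {
    bleed <- tr$bleeds > 0
    expect_true(all(tr$tissue[bleed]))
    expect_equal(sum(tr$artifacts & bleed), 0)
  }
})

test_that("misalignment is bounded and zero bounds give identity", {
  cfg0 <- tiny_sim()
  st0 <- generate_stack(cfg0)
  for (tf in st0$transforms) {
    expect_equal(tf$angle_deg, 0)
    expect_equal(c(tf$drow, tf$dcol), c(0, 0))
  }
  cfg <- tiny_sim(misalignment_translation_px = 7,
                  misalignment_rotation_deg = 2.5, n_sections = 10L)
  st <- generate_stack(cfg)
  for (tf in st$transforms) {
    expect_lte(abs(tf$angle_deg), 2.5)
    expect_lte(max(abs(c(tf$drow, tf$dcol))), 7)
  }
  expect_gt(max(abs(vapply(st$transforms, `[[`, 0, "drow"))), 0)
})

test_that("planted bleed areas match the circular-equivalent area", {
  cfg <- slide_sim_config(n_sections = 8L, n_bleeds_total = 24L, rng_seed = 3L)
  st <- generate_stack(cfg)
  obj <- st$objects
  big_enough <- obj$diameter_um >= 5 * cfg$pixel_size_um
  expected <- pi * (obj$diameter_um / 2)^2
  rel_err <- abs(obj$area_um2 - expected) / expected
  expect_true(all(rel_err[big_enough] <= 0.10))
})

test_that("sections sample one smooth 3D silhouette with a ventricle", {
  cfg <- tiny_sim(n_sections = 6L)
  st <- generate_stack(cfg)
  areas <- vapply(st$truth, function(t) sum(t$tissue), 0)
  # slowly varying cross-section: consecutive change well under 5%
  expect_true(all(abs(diff(areas)) / areas[-1] < 0.05))
  # at least one interior hole: filling holes adds pixels
  t1 <- st$truth[[3]]$tissue
  expect_gt(sum(fill_holes(t1)), sum(t1))
})

test_that("synthetic datasets round-trip to disk", {
  dir <- withr::local_tempdir()
  cfg <- tiny_sim(n_sections = 2L)
  st <- generate_stack(cfg)
  write_synthetic_dataset(st, dir)
  expect_true(file.exists(file.path(dir, "sec_0001.tif")))
  expect_true(file.exists(file.path(dir, "ground_truth_objects.csv")))
  img <- tiff::readTIFF(file.path(dir, "sec_0002.tif")) * 255
  expect_equal(round(img), st$images[[2]], tolerance = 1e-6,
               ignore_attr = TRUE)
  csv <- read.csv(file.path(dir, "ground_truth_objects.csv"))
  expect_equal(nrow(csv), nrow(st$objects))
})
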