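# Random-forest pixel classification: features, training, inference,
# serialization, batch segmentation.

test_that("feature extraction honours the descriptor contract", {
  desc <- default_feature_descriptor()
  flat <- array(77, c(20, 24, 3))
  fm <- extract_features(flat, desc)
  expect_equal(ncol(fm), 3 * length(desc$filters))
  expect_equal(nrow(fm), 20 * 24)
  # constant image: blur features constant, derivative features zero
  for (f in c("gauss_2", "gauss_8")) {
    expect_lt(max(abs(fm[, paste0("ch1_", f)] - 77)), 1e-9)
  }
  expect_equal(max(abs(fm[, "ch2_gradient"])), 0)
  expect_equal(max(abs(fm[, "ch3_laplacian"])), 0)

  expect_error(extract_features(flat, list(filters = "swirl")),
               class = "cmhq_config_error")
  expect_error(extract_features(flat, list(filters = character())),
               class = "cmhq_config_error")
})

test_that("Gaussian feature matches a dense convolution oracle", {
  withr::with_seed(5, img <- matrix(runif(40 * 40, 0, 255), 40, 40))
  sigma <- 2
  rad <- ceiling(3 * sigma)
  k1 <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  oracle <- matrix(NA_real_, 40, 40)
  for (r in (rad + 1):(40 - rad)) {
    for (c in (rad + 1):(40 - rad)) {
      oracle[r, c] <- sum(img[(r - rad):(r + rad), (c - rad):(c + rad)] * k2)
    }
  }
  rgb <- array(rep(img, 3), c(40, 40, 3))
  fm <- extract_features(rgb, list(filters = "gauss_2"))
  got <- matrix(fm[, 1], 40, 40)
  interior <- (rad + 1):(40 - rad)
  expect_equal(got[interior, interior], oracle[interior, interior],
               tolerance = 1e-5)
})

test_that("training separates the three stain classes and is seeded", {
  cfg <- tiny_sim(n_bleeds_total = 3L, n_sections = 2L, artifact_rate = 1,
                  noise_sd = 2)
  st <- generate_stack(cfg)
  anns <- lapply(1:2, function(i) annotate_from_truth(st$truth[[i]], seed = i))
  model <- train_pixel_classifier(anns, st$images, n_trees = 60L)
  expect_gte(model$training_accuracy, 0.99)

  held <- generate_section(tiny_sim(n_bleeds_total = 2L, rng_seed = 77L), 1)
  p1 <- predict_labels(model, held$image)
  model2 <- train_pixel_classifier(anns, st$images, n_trees = 60L)
  expect_identical(p1, predict_labels(model2, held$image))

  only_bleed <- lapply(anns, function(a) a[a$class == "bleed", ])
  expect_error(train_pixel_classifier(only_bleed, st$images),
               "tissue", class = "cmhq_training_error")
})

test_that("label maps use exactly the 0/1/2 code contract", {
  model <- test_classifier()
  blank <- array(255, c(50, 60, 3))
  lab <- predict_labels(model, blank)
  expect_true(all(lab == 0L))

  lab2 <- matrix(c(0L, 1L, 1L, 2L), 2, 2)
  bm <- labels_to_bleed_mask(lab2)
  expect_equal(sum(bm), sum(lab2 == 2L))
  expect_false(any(bm & (lab2 == 1L)))
  expect_error(labels_to_bleed_mask(matrix(3L, 2, 2)),
               class = "cmhq_data_error")
})

test_that("classifier detects planted bleeds on held-out sections", {
  model <- test_classifier()
  cfg <- slide_sim_config(n_sections = 2L, n_bleeds_total = 8L,
                          artifact_rate = 2, rng_seed = 909L)
  st <- generate_stack(cfg)
  detected <- areas <- c()
  true_area <- pred_area <- 0
  for (i in 1:2) {
    lab <- predict_labels(model, st$images[[i]])
    bm <- labels_to_bleed_mask(lab)
    mo <- match_objects(st$truth[[i]]$bleeds, bm)
    detected <- c(detected, mo$detected)
    true_area <- true_area + sum(st$truth[[i]]$bleeds > 0)
    pred_area <- pred_area + sum(bm)
  }
  expect_gte(mean(detected), 0.75)
  # conservative strokes: predicted bleed area slightly under ground truth
  expect_lt(pred_area / true_area, 1.05)
})

test_that("models survive a save/load round trip", {
  model <- test_classifier()
  path <- withr::local_tempfile(fileext = ".rds")
  save_pixel_classifier(model, path)
  back <- load_pixel_classifier(path)
  img <- generate_section(tiny_sim(rng_seed = 55L), 1)$image
  expect_identical(predict_labels(model, img), predict_labels(back, img))
  expect_error(load_pixel_classifier(
    withr::local_tempfile(fileext = ".rds", lines = "")), )
})

test_that("batch segmentation renames, orders and is repeatable", {
  model <- test_classifier()
  indir <- withr::local_tempdir()
  outdir1 <- withr::local_tempdir()
  outdir2 <- withr::local_tempdir()
  cfg <- tiny_sim(n_sections = 2L, n_bleeds_total = 2L)
  st <- generate_stack(cfg)
  tiff::writeTIFF(st$images[[1]] / 255, file.path(indir, "brain_12.tif"))
  tiff::writeTIFF(st$images[[2]] / 255, file.path(indir, "brain_3.tif"))
  mf <- batch_segment(model, indir, outdir1)
  expect_equal(mf$original, c("brain_3.tif", "brain_12.tif")) # numeric order
  expect_equal(mf$canonical, c("sec_0003.tif", "sec_0012.tif"))
  expect_true(all(file.exists(file.path(outdir1,
                                        c("labels_0003.tif", "labels_0012.tif")))))
  batch_segment(model, indir, outdir2)
  expect_identical(
    readBin(file.path(outdir1, "labels_0003.tif"), "raw", 1e6),
    readBin(file.path(outdir2, "labels_0003.tif"), "raw", 1e6)
  )
  expect_error(batch_segment(model, withr::local_tempdir(), outdir1),
               "no input", class = "cmhq_data_error")
  # duplicate indices are a hard error
  tiff::writeTIFF(st$images[[1]] / 255, file.path(indir, "extra_003.tif"))
  expect_error(batch_segment(model, indir, outdir1),
               class = "cmhq_data_error")
})
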