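# 3D assembly: downscaling, surface mask, overlay, volume, quantification.

label_stack_from <- function(st, cfg) {
  labs <- lapply(st$truth, function(t) masks_to_labels(t$tissue, t$bleeds > 0))
  standardize_canvas(labs, cfg$pixel_size_um)
}

test_that("majority-vote downscale keeps codes and favours bleeds on ties", {
  cfg <- tiny_sim()
  st <- label_stack_from(generate_stack(cfg), cfg)
  expect_identical(downscale_stack(st, 1L), st)

  uni <- new_stack(list(matrix(1L, 25, 25)), 1)
  expect_true(all(downscale_stack(uni, 5L)$images[[1]] == 1L))

  # 13 of 25 bleed pixels win the block
  block <- matrix(1L, 5, 5)
  block[1:13] <- 2L
  s <- new_stack(list(block), 1)
  expect_equal(as.vector(downscale_stack(s, 5L)$images[[1]]), 2L)

  # exact tie background/bleed resolves to the higher code
  tie <- matrix(0L, 4, 4)
  tie[1:8] <- 2L
  s2 <- new_stack(list(tie), 1)
  expect_equal(as.vector(downscale_stack(s2, 4L)$images[[1]]), 2L)

  expect_equal(downscale_stack(s, 5L)$pixel_size_um, 5)
  expect_error(downscale_stack(s, 10L), class = "cmhq_config_error")
})

test_that("brain mask is one smooth component matching the tissue", {
  # solid ellipse per section
  nr <- 80; nc <- 100
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ell <- ((rr - 40) / 28)^2 + ((cc - 50) / 38)^2 <= 1
  labs <- replicate(5, {
    m <- matrix(0L, nr, nc)
    m[ell] <- 1L
    m
  }, simplify = FALSE)
  # a far-away one-pixel noise speck
  labs[[3]][5, 5] <- 2L
  stack <- new_stack(labs, 1)
  mask <- build_brain_mask(stack, sigma = 2)
  dice <- 2 * sum(mask[[2]] & ell) / (sum(mask[[2]]) + sum(ell))
  expect_gte(dice, 0.98)
  expect_false(mask[[3]][5, 5]) # largest-component rule drops the speck
  # single 3D connected component
  arr <- array(FALSE, c(5, nr, nc))
  for (z in 1:5) arr[z, , ] <- mask[[z]]
  lab3 <- cmhq:::cpp_label_components_3d(as.vector(arr), 5L, nr, nc)
  expect_equal(attr(lab3, "n"), 1L)
  expect_error(build_brain_mask(new_stack(list(), 1)),
               class = "cmhq_data_error")
})

test_that("minimum overlay only removes and never adds", {
  lab <- matrix(c(0L, 1L, 2L, 2L), 2, 2)
  st <- new_stack(list(lab), 1)
  all_true <- list(matrix(TRUE, 2, 2))
  expect_equal(minimum_overlay(st, all_true)$images[[1]], lab)
  all_false <- list(matrix(FALSE, 2, 2))
  expect_true(all(minimum_overlay(st, all_false)$images[[1]] == 0L))
  half <- list(matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
  out <- minimum_overlay(st, half)$images[[1]]
  expect_equal(out[1, 2], 2L) # bleed inside mask survives
  expect_equal(out[2, 2], 0L) # identical code outside mask removed
  expect_lte(sum(out == 2L), sum(lab == 2L))
  expect_error(minimum_overlay(st, list(matrix(TRUE, 3, 3))),
               class = "cmhq_data_error")
})

test_that("volume assembly conserves voxels and computes depth", {
  cfg <- tiny_sim(n_sections = 8L, n_bleeds_total = 4L)
  st <- label_stack_from(generate_stack(cfg), cfg)
  vol <- assemble_volume(st, z_spacing_um = 20)
  expect_equal(dim(vol)[1] * attr(vol, "voxel_size_um")[["z"]] / 1000, 0.16)
  for (k in 0:2) {
    expect_equal(sum(vol == k),
                 sum(vapply(st$images, function(m) sum(m == k), 0)))
  }
  # 3D merging can only reduce object count
  n2d <- sum(vapply(st$images, function(m) {
    nrow(analyze_particles(m == 2L, 1, min_area_um2 = 0))
  }, 0))
  expect_lte(count_bleed_objects_3d(vol), n2d)
})

test_that("burden quantification follows its defining arithmetic", {
  lab <- matrix(0L, 40, 40)
  lab[1:990] <- 1L
  lab[991:1000] <- 2L
  st <- new_stack(list(lab), 1000) # 1 px = 1000 um -> 1 mm2 per px
  q <- quantify_cmh(st, min_area_um2 = 0)
  per <- q[1, ]
  expect_equal(per$area_fraction_pct, 1.0)

  # 5 objects in 2 mm2 of tissue -> density 2.5 per mm2
  lab2 <- matrix(0L, 50, 50)
  lab2[1:2000] <- 1L
  for (k in 0:4) lab2[10 + 2 * k, 45] <- 2L
  px <- sqrt(2 / 2005) * 1000 # tissue+bleed pixels cover 2 mm2
  q2 <- quantify_cmh(new_stack(list(lab2), px), min_area_um2 = 0)
  expect_equal(q2$count[1], 5)
  expect_equal(q2$density_per_mm2[1], 2.5, tolerance = 1e-9)

  # aggregate pools sections (tissue-area weighting)
  st3 <- new_stack(list(lab, lab), 1000)
  q3 <- quantify_cmh(st3, min_area_um2 = 0)
  agg <- q3[is.na(q3$section), ]
  expect_equal(agg$tissue_area_mm2, 2 * q3$tissue_area_mm2[1])
  expect_equal(agg$area_fraction_pct, 1.0)

  expect_error(quantify_cmh(new_stack(list(matrix(0L, 4, 4)), 1)),
               class = "cmhq_degenerate_error")
})
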