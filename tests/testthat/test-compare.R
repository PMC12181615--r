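# Comparison harness: ratios, ANOVA/Dunnett, Kruskal-Wallis/Dunn, timing.

fake_summary <- function(counts, areas) {
  data.frame(section = seq_along(counts), count = counts, area_um2 = areas)
}

test_that("ratios to the reference follow the zero-handling contract", {
  ref <- fake_summary(c(2, 0, 3, 0), c(20, 0, 30, 0))
  same <- ratio_to_reference(ref, ref)
  expect_equal(same$count_ratio, rep(1, 4)) # 0/0 -> exact agreement
  expect_equal(same$area_ratio, rep(1, 4))
  expect_equal(attr(same, "n_excluded"), 0L)

  doubled <- fake_summary(c(4, 0, 6, 1), c(40, 0, 60, 5))
  r <- ratio_to_reference(doubled, ref)
  expect_equal(r$count_ratio[1], 2)
  expect_true(is.infinite(r$count_ratio[4]))
  expect_true(r$excluded[4])
  expect_equal(attr(r, "n_excluded"), 1L)
  expect_equal(mean(r$count_ratio[!r$excluded]), 5 / 3) # ratios 2, 1, 2

  expect_error(ratio_to_reference(fake_summary(1, 1), ref),
               class = "cmhq_data_error")
})

test_that("ANOVA statistic matches a hand-computed three-group fixture", {
  # three methods x 4 sections, values chosen for hand computation
  vals <- list(
    reference = c(1, 1, 1, 1),
    a = c(1.1, 0.9, 1.2, 0.8),
    b = c(2.0, 2.2, 1.8, 2.0)
  )
  # textbook one-way ANOVA
  all_v <- unlist(vals)
  g_mean <- mean(all_v)
  ss_between <- sum(vapply(vals, function(v) length(v) * (mean(v) - g_mean)^2, 0))
  ss_within <- sum(vapply(vals, function(v) sum((v - mean(v))^2), 0))
  f_hand <- (ss_between / 2) / (ss_within / 9)

  ratios <- lapply(vals[c("a", "b")], function(v) {
    structure(
      data.frame(section = 1:4, count_ratio = v, area_ratio = v,
                 excluded = FALSE),
      n_excluded = 0L
    )
  })
  cmp <- compare_methods(ratios, metric = "count")
  expect_equal(cmp$count$anova_F, f_hand, tolerance = 1e-6)

  # inflated method flagged, faithful method not
  expect_lt(cmp$count$summary$p_vs_reference[
    cmp$count$summary$method == "b"], 0.001)
  expect_gt(cmp$count$summary$p_vs_reference[
    cmp$count$summary$method == "a"], 0.05)
})

test_that("identical methods yield no significant Dunnett contrast", {
  ratios <- lapply(1:2, function(k) {
    structure(
      data.frame(section = 1:10, count_ratio = 1, area_ratio = 1,
                 excluded = FALSE),
      n_excluded = 0L
    )
  })
  names(ratios) <- c("m1", "m2")
  cmp <- compare_methods(ratios)
  ps <- cmp$count$summary$p_vs_reference
  expect_true(all(ps[!is.na(ps)] > 0.05))
  # reference's own ratios are exactly 1 with SEM 0
  refrow <- cmp$count$summary[cmp$count$summary$method == "reference", ]
  expect_equal(refrow$mean_ratio, 1)
  expect_equal(refrow$sem, 0)
  # deterministic report
  cmp2 <- compare_methods(ratios)
  expect_identical(cmp, cmp2)
})

test_that("a grossly inflated method is detected at n = 30 sections", {
  withr::with_seed(17, {
    good <- structure(
      data.frame(section = 1:30, count_ratio = rnorm(30, 1, 0.1),
                 area_ratio = rnorm(30, 1, 0.1), excluded = FALSE),
      n_excluded = 0L
    )
    bad <- structure(
      data.frame(section = 1:30, count_ratio = rnorm(30, 100, 30),
                 area_ratio = rnorm(30, 100, 30), excluded = FALSE),
      n_excluded = 0L
    )
  })
  cmp <- compare_methods(list(good = good, bad = bad))
  s <- cmp$count$summary
  expect_lt(s$p_vs_reference[s$method == "bad"], 0.001)
})

test_that("group comparison detects strong burden differences only", {
  # 10x planted burden separates aged from young at n = 3 per group
  detect <- vapply(1:60, function(seed) {
    withr::with_seed(seed, {
      burden <- data.frame(
        group = rep(c("young", "aged"), each = 3),
        brain = 1:6,
        area_fraction_pct = c(rlnorm(3, log(0.002), 0.5),
                              rlnorm(3, log(0.02), 0.5))
      )
    })
    compare_groups(burden)$area_fraction_pct$kw_p < 0.05
  }, NA)
  expect_gte(mean(detect), 0.8)

  # equal planted burden: no significant difference
  withr::with_seed(99, {
    burden <- data.frame(
      group = rep(c("aged", "treated"), each = 3),
      brain = 1:6,
      density_per_mm2 = rlnorm(6, log(12), 0.4)
    )
  })
  rep0 <- compare_groups(burden)
  expect_gt(rep0$density_per_mm2$kw_p, 0.05)

  expect_error(compare_groups(data.frame(
    group = "a", brain = 1:3, density_per_mm2 = 1:3
  )), class = "cmhq_stats_error")
  expect_error(compare_groups(data.frame(
    group = c("a", "a", "a", "b", "b"), brain = 1:5,
    density_per_mm2 = 1:5
  )), class = "cmhq_stats_error")
})

test_that("Kruskal-Wallis holds its nominal type-I error", {
  rejections <- vapply(1:400, function(seed) {
    withr::with_seed(seed, {
      v <- rnorm(24)
      g <- rep(c("a", "b", "c"), each = 8)
    })
    kruskal.test(v, factor(g))$p.value < 0.05
  }, NA)
  expect_lt(abs(mean(rejections) - 0.05), 0.025)
})

test_that("timing profile records stages without asserting durations", {
  tm <- new_timing()
  x <- time_stage(tm, "one", {
    Sys.sleep(0.01)
    41 + 1
  })
  expect_equal(x, 42)
  time_stage(tm, "two", TRUE)
  tab <- timing_table(tm)
  expect_equal(tab$stage, c("one", "two"))
  expect_true(all(tab$seconds >= 0))
})
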