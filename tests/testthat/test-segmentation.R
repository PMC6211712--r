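# The four segmentation methods and batch processing.

default_gen <- generate_image(synthetic_spec(seed = 7))

test_that("seg_config validates its parameters", {
  expect_error(seg_config(smooth_kernel = 4), "odd")
  expect_error(seg_config(low_pct = 70, high_pct = 20), "low_pct")
  expect_error(seg_config(moran_kernel = 1), "odd")
  cfg <- seg_config()
  expect_equal(cfg$method, "percentile")
  expect_equal(cfg$smooth_kernel, 7L)
})

test_that("first-difference segmentation isolates a narrow cytoplasm band", {
  spec <- synthetic_spec(seed = 31, cytoplasm_mean = 0.5,
                         cytoplasm_sd = 0.02)
  gen <- generate_image(spec)
  res <- segment_first_difference(gen$image, seg_config("first_diff"))
  ret <- res$segmented$valid
  purity <- mean(gt_mask(gen$truth, "cytoplasm")[ret])
  expect_gte(purity, 0.99)
  expect_equal(res$low_threshold, res$high_threshold - 0.14,
               tolerance = 1e-12)

  # degenerate zero offset leaves a measure-zero band: near-empty result
  res0 <- segment_first_difference(gen$image,
                                   seg_config("first_diff", offset = 0))
  expect_lt(res0$stats$n, 0.01 * sum(gen$image$valid))
})

test_that("first-difference segmentation reduces skewness", {
  for (seed in c(7, 19)) {
    gen <- generate_image(synthetic_spec(seed = seed))
    res <- segment_first_difference(gen$image, seg_config("first_diff"))
    raw_skew <- image_stats(gen$image)$skewness
    expect_lt(abs(res$stats$skewness), abs(raw_skew))
  }
})

test_that("second difference agrees with first difference", {
  for (seed in c(7, 19, 23)) {
    gen <- generate_image(synthetic_spec(seed = seed))
    r1 <- segment_first_difference(gen$image, seg_config("first_diff"))
    r2 <- segment_second_difference(gen$image, seg_config("second_diff"))
    # the downward-crossing-derived center equals the optimum
    expect_equal(r2$low_threshold, r1$low_threshold, tolerance = 1e-12)
    expect_lt(abs(r2$stats$mean - r1$stats$mean), 0.05)
  }
})

test_that("second difference is inapplicable without crossings", {
  # strictly accelerating profile: all-positive second difference
  p <- fake_profile_sd(rep(0.01, 20))
  expect_equal(nrow(find_root_crossings(p)), 0)
  # an image whose intensities make a monotone profile: two far-apart spikes
  m <- matrix(rep(c(0.2, 0.9), each = 128), 16)
  img <- raster_image(m)
  expect_error(segment_second_difference(img, seg_config("second_diff")),
               "inapplicable|no optimum")
})

test_that("percentile segmentation with kernel 1 retains the band fraction", {
  set.seed(14)
  n <- 3600
  img <- raster_image(matrix(sample(seq(0.05, 0.95, length.out = n)), 60))
  cfg <- seg_config("percentile", smooth_kernel = 1L)
  res <- segment_percentile(img, cfg)
  expect_lt(abs(res$stats$n / n - 0.5), 2 / sqrt(n))  # 70 - 20 = 50%
})

test_that("percentile defaults isolate cytoplasm and shrink the variance", {
  gen <- default_gen
  res <- segment_percentile(gen$image, seg_config("percentile"))
  ret <- res$segmented$valid
  expect_lt(mean(gt_mask(gen$truth, "vessel")[ret]), 0.05)
  expect_gt(mean(gt_mask(gen$truth, "cytoplasm")[ret]), 0.5)
  raw <- image_stats(gen$image)
  expect_lt(res$stats$sd, raw$sd)
  expect_lt(abs(res$stats$skewness), abs(raw$skewness))
})

test_that("moran segmentation matches percentile segmentation closely", {
  gen <- default_gen
  mo <- segment_moran(gen$image, seg_config("moran"))
  pc <- segment_percentile(gen$image, seg_config("percentile"))
  d_methods <- dice(mo$segmented$valid, pc$segmented$valid)
  d_vessel <- dice(mo$segmented$valid, gt_mask(gen$truth, "vessel"))
  expect_gt(d_methods, d_vessel)
  expect_gt(d_methods, 0.8)
  raw <- image_stats(gen$image)
  expect_lt(abs(mo$stats$skewness), abs(raw$skewness))

  # cutoff below the minimum Moran value retains nothing
  lm <- local_moran(gen$image, 7)
  below <- min(lm$value[lm$valid]) - 1
  mo0 <- segment_moran(gen$image, seg_config("moran", moran_cutoff = below))
  expect_equal(mo0$stats$n, 0L)

  expect_error(segment_moran(raster_image(matrix(0.4, 16, 16)),
                             seg_config("moran")), "degenerate")
})

test_that("thresholds come from the original image, not the mask", {
  gen <- default_gen
  # the smoothing kernel only changes the mask; thresholds must not move
  r7 <- segment_percentile(gen$image, seg_config("percentile"))
  r15 <- segment_percentile(gen$image,
                            seg_config("percentile", smooth_kernel = 15L))
  expect_identical(r7$low_threshold, r15$low_threshold)
  expect_identical(r7$high_threshold, r15$high_threshold)
  f7 <- segment_first_difference(gen$image, seg_config("first_diff"))
  f15 <- segment_first_difference(
    gen$image, seg_config("first_diff", smooth_kernel = 15L))
  expect_identical(f7$low_threshold, f15$low_threshold)
})

test_that("segmentation is deterministic and idempotent", {
  gen <- default_gen
  cfg <- seg_config("percentile")
  a <- segment_image(gen$image, cfg)
  b <- segment_image(gen$image, cfg)
  expect_identical(a$segmented, b$segmented)

  # re-selecting the output with the same thresholds and kernel 1 keeps
  # exactly the same pixel set
  seg <- a$segmented
  mask1 <- focal_apply(gen$image, cfg$smooth_kernel)
  again <- select_between(seg, mask1, a$low_threshold, a$high_threshold)
  expect_identical(again$valid, seg$valid)
})

test_that("widening the percentile interval never shrinks the result", {
  gen <- default_gen
  n_prev <- -1L
  for (width in list(c(30, 60), c(20, 70), c(10, 80), c(5, 90))) {
    res <- segment_percentile(gen$image,
                              seg_config("percentile", low_pct = width[1],
                                         high_pct = width[2]))
    expect_gte(res$stats$n, n_prev)
    n_prev <- res$stats$n
  }
})

test_that("every method reports internally consistent results", {
  gen <- default_gen
  for (method in c("percentile", "first_diff", "second_diff", "moran")) {
    res <- segment_image(gen$image, seg_config(method))
    expect_identical(res$stats$n, image_stats(res$segmented)$n)
    expect_lte(res$low_threshold, res$high_threshold)
    # retained mask values lie inside the reported thresholds
    mask <- if (method == "moran")
      local_moran(gen$image, res$config$moran_kernel)
    else focal_apply(gen$image, res$config$smooth_kernel)
    mv <- mask$value[res$segmented$valid]
    expect_true(all(mv >= res$low_threshold & mv <= res$high_threshold))
  }
})

test_that("segment_batch records per-file outcomes in input order", {
  empty <- segment_batch(character(), seg_config())
  expect_equal(nrow(empty$summary), 0)

  dir <- withr::local_tempdir()
  spec <- synthetic_spec(seed = 41, width = 96L, height = 96L)
  stack <- generate_stack(spec, 3)
  paths <- character(3)
  for (k in 1:3) {
    paths[k] <- file.path(dir, sprintf("slice_%d.tif", k))
    write_segmented(stack[[k]]$image, paths[k])
  }
  bad <- file.path(dir, "broken.tif")
  writeLines("not a tiff", bad)

  cfg <- seg_config("percentile")
  batch <- segment_batch(c(paths, bad), cfg)
  expect_equal(batch$summary$file, c(paths, bad))
  expect_true(all(is.na(batch$summary$error[1:3])))
  expect_false(is.na(batch$summary$error[4]))

  # batch rows equal single-image runs of the same config
  for (k in 1:3) {
    single <- segment_image(read_image(paths[k]), cfg)
    expect_equal(batch$summary$mean[k], single$stats$mean)
    expect_equal(batch$summary$n_retained[k], single$stats$n)
  }
})
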