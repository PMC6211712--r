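# Histogram-space machinery: integrated intensity, differences, landmarks,
# percentile curve and plateau analysis.

test_that("build_profile integrates frequency times bin midpoint", {
  flat <- raster_image(matrix(0.505, 8, 8))
  p <- build_profile(flat)
  expect_equal(p$integrated[51:100], rep(0.505, 50))  # jumps at bin 51
  expect_equal(p$integrated[50], 0)

  g <- random_image(48, 48, seed = 8)
  p2 <- build_profile(g)
  x <- g$intensity[g$valid]
  expect_equal(p2$integrated, oracle_integrated(x), tolerance = 1e-12)
  # conservation: final value is the mean of midpoint-quantized intensities
  quantized <- p2$mids[pmin(floor(x * 100) + 1, 100)]
  expect_equal(p2$integrated[100], mean(quantized), tolerance = 1e-12)
  expect_equal(sum(p2$frequency), 1)
  expect_true(all(diff(p2$integrated) >= 0))

  empty <- raster_image(matrix(0.5, 3, 3), matrix(FALSE, 3, 3))
  expect_error(build_profile(empty), "empty")
})

test_that("differences reconstruct the integrated vector", {
  g <- random_image(32, 32, seed = 9)
  p <- build_profile(g)
  expect_length(p$integrated, 100)
  expect_length(p$first_diff, 99)
  expect_length(p$second_diff, 98)
  expect_equal(p$integrated[1] + cumsum(p$first_diff), p$integrated[-1],
               tolerance = 1e-12)
  expect_equal(p$first_diff[1] + cumsum(p$second_diff), p$first_diff[-1],
               tolerance = 1e-12)
})

test_that("profiles are invariant to pixel ordering", {
  g <- random_image(24, 24, seed = 10, invalid_frac = 0)
  set.seed(1)
  shuffled <- raster_image(matrix(sample(g$intensity), 24, 24))
  expect_equal(build_profile(g)$integrated,
               build_profile(shuffled)$integrated)
  expect_equal(build_percentile_curve(g)$intensity,
               build_percentile_curve(shuffled)$intensity)
})

test_that("find_optimum locates the interior maximum of the first diff", {
  p <- fake_profile_fd(c(1, 2, 5, 3, 4) / 100)
  opt <- find_optimum(p)
  expect_equal(opt$index, 3L)
  expect_equal(opt$intensity, p$mids[4])

  expect_error(find_optimum(fake_profile_fd((1:6) / 100)), "no optimum")
})

test_that("root crossings follow sign bookkeeping with zero attachment", {
  cr <- find_root_crossings(fake_profile_sd(c(1, 1, -1, -1, 1) / 10))
  expect_equal(cr$direction, c("down", "up"))
  expect_equal(cr$index, c(3L, 5L))

  expect_equal(nrow(find_root_crossings(fake_profile_sd(rep(0.02, 8)))), 0)

  # exact zeros attach to the following sign
  cr0 <- find_root_crossings(fake_profile_sd(c(0.1, 0, -0.1, -0.1)))
  expect_equal(cr0$direction, "down")
  expect_equal(cr0$index, 2L)
})

test_that("ascending crossings on flat tails are asymptote-terminated", {
  # a real up-crossing with substantial values afterwards survives
  sd_live <- c(0.01, -0.01, 0.01, 0.01, 0.01, 0.01, 0.01)
  cr <- find_root_crossings(fake_profile_sd(sd_live))
  expect_true("up" %in% cr$direction)

  # an up-crossing into a flat tail (|sd| < eps for the run) is suppressed
  sd_flat <- c(0.01, -0.01, 5e-5, 5e-5, 5e-5, 5e-5, 5e-5, 5e-5)
  cr2 <- find_root_crossings(fake_profile_sd(sd_flat))
  expect_false("up" %in% cr2$direction)
  # with a stricter eps it reappears
  cr3 <- find_root_crossings(fake_profile_sd(sd_flat), eps = 1e-6)
  expect_true("up" %in% cr3$direction)
})

test_that("the optimum coincides with the primary downward root crossing", {
  for (seed in c(1, 5, 9, 13)) {
    gen <- generate_image(synthetic_spec(seed = seed))
    p <- build_profile(gen$image)
    opt <- find_optimum(p)
    cr <- find_root_crossings(p)
    down <- cr[cr$direction == "down", ]
    primary <- down[which.max(p$first_diff[down$index]), ]
    expect_equal(primary$index, opt$index)
    expect_equal(primary$intensity, opt$intensity)
  }
})

test_that("optimum of a default synthetic profile sits in the cytoplasm band", {
  spec <- synthetic_spec(seed = 21)
  gen <- generate_image(spec)
  opt <- find_optimum(build_profile(gen$image))
  expect_gt(opt$intensity, spec$cytoplasm_mean - 2 * spec$cytoplasm_sd)
  expect_lt(opt$intensity, spec$cytoplasm_mean + 2 * spec$cytoplasm_sd)
})

test_that("percentile curve equals the order-statistic oracle", {
  # fine uniform grid: entry p sits within one grid step of p/100
  n <- 4096
  g <- raster_image(matrix(seq(0, 1, length.out = n), 64, 64))
  curve <- build_percentile_curve(g)
  expect_lt(abs(curve$intensity[20] - 0.2), 1 / 63)
  expect_lt(abs(curve$intensity[70] - 0.7), 1 / 63)
  expect_equal(curve$intensity[100], max(g$intensity))
  expect_true(all(diff(curve$intensity) >= 0))

  img <- random_image(50, 50, seed = 12)
  cv <- build_percentile_curve(img)
  xs <- sort(img$intensity[img$valid])  # full-sort brute force
  nn <- length(xs)
  expect_equal(cv$intensity, xs[ceiling((1:100) * nn / 100)])

  tiny <- raster_image(matrix(runif(81), 9, 9),
                       matrix(c(rep(TRUE, 50), rep(FALSE, 31)), 9, 9))
  expect_error(build_percentile_curve(tiny), "insufficient")
})

test_that("percentile curve inverts the empirical distribution function", {
  g <- random_image(40, 40, seed = 13)
  x <- g$intensity[g$valid]
  curve <- build_percentile_curve(g)
  for (p in c(10, 25, 50, 75, 90)) {
    t <- curve$intensity[p]
    pct_at_t <- mean(x <= t) * 100
    expect_gte(pct_at_t, p)   # at least p% at or below entry p
    expect_lt(pct_at_t - p, 1)  # and no more than one percentile bin over
  }
})

test_that("pixels-per-bin metadata reflects whole-image bin arithmetic", {
  img <- raster_image(matrix(runif(1024 * 512, 0.2, 0.8), 512))
  expect_equal(build_percentile_curve(img)$pixels_per_bin,
               round(1024 * 512 / 100))
})

test_that("count_zeros folds zeroed gross-segmented pixels back in", {
  m <- matrix(runif(400, 0.3, 0.9), 20)
  m[, 1:4] <- 0
  img <- raster_image(m, m != 0)
  c1 <- build_percentile_curve(img)
  c2 <- build_percentile_curve(img, count_zeros = TRUE)
  expect_equal(c1$n, 320L)
  expect_equal(c2$n, 400L)
  expect_equal(c2$intensity[10], 0)  # 20% zeros swamp the low percentiles
  expect_gt(c1$intensity[10], 0)
})

test_that("find_plateau spans the low-delta basin", {
  mk_curve <- function(delta) {
    structure(list(intensity = cumsum(c(0.1, delta)) / 100, delta = delta,
                   n = 10000L, pixels_per_bin = 100L),
              class = "percentile_curve")
  }
  pl <- find_plateau(mk_curve(c(9, 9, 1, 1, 1, 1, 9, 9)))
  expect_equal(pl$low_pct, 3L)
  expect_equal(pl$high_pct, 7L)

  flat <- mk_curve(rep(2, 8))
  pf <- find_plateau(flat)
  expect_equal(pf$low_pct, 1L)
  expect_equal(pf$high_pct, 9L)

  expect_error(find_plateau(mk_curve(c(9, 1, 9, 1, 9, 1, 9, 1))),
               "no plateau")
})

test_that("plateau percentiles are stable across brightness sweeps", {
  pcts <- sapply(c(0.5, 1.0, 1.4), function(b) {
    gen <- generate_image(synthetic_spec(seed = 17, brightness_scale = b))
    pl <- find_plateau(build_percentile_curve(gen$image))
    c(pl$low, pl$high, pl$low_pct, pl$high_pct)
  })
  # intensity endpoints track brightness while percentiles barely move
  expect_gt(diff(range(pcts[2, ])), 0.1)
  expect_lte(diff(range(pcts[3, ])), 10)
  expect_lte(diff(range(pcts[4, ])), 10)
})
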