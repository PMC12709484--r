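test_that("sweep of a constant image steps from plane-filling to undefined", {
  img <- matrix(128L, 120, 120)
  grid <- threshold_grid(118, 133, 5) # 118,123,128 <= 128 < 133
  curve <- sweep_df(img, grid, region_size = 60)
  expect_equal(curve$mean_df[1:3], rep(2, 3), tolerance = 1e-6)
  expect_true(is.na(curve$mean_df[4])) # empty masks stay as gaps
  expect_equal(nrow(curve), 4) # undefined entry kept in the curve
})

test_that("aggregation pools regions so duplicated images change nothing", {
  img <- make_pseudo_tissue(size = 96, severity = 0.5, seed = 5)
  grid <- threshold_grid(60, 90, 15)
  one <- sweep_df(list(img), grid, region_size = 48)
  two <- sweep_df(list(img, img), grid, region_size = 48)
  expect_equal(two$mean_df, one$mean_df)
  # duplicated values change the sample std only by the exact ddof factor
  n <- one$n_regions
  expect_equal(two$std_df, one$std_df * sqrt(2 * (n - 1) / (2 * n - 1)))
})

test_that("optimal_threshold maximizes |diff| with low-threshold tie-break", {
  img <- make_pseudo_tissue(size = 96, severity = 0, seed = 3)
  grid <- threshold_grid(60, 100, 20)
  a <- sweep_df(img, grid, region_size = 48)
  opt <- optimal_threshold(a, a, "mean")
  expect_equal(opt$abs_diff, 0)
  expect_equal(opt$gray_level, 60) # tie -> lowest threshold

  b <- a
  b$mean_df <- b$mean_df + c(0.01, 0.05, -0.02)
  opt2 <- optimal_threshold(a, b, "mean")
  expect_equal(opt2$gray_level, 80)
  expect_equal(opt2$abs_diff, 0.05)
  expect_equal(opt2$percent_change,
               100 * 0.05 / a$mean_df[2])
})

test_that("optimal_threshold is invariant to image order within groups", {
  ctrl <- small_cohort(0, 1:3)
  dis <- small_cohort(1, 11:13)
  grid <- threshold_grid(80, 120, 20)
  o1 <- optimal_threshold(sweep_df(ctrl, grid, 48),
                          sweep_df(dis, grid, 48), "mean")
  o2 <- optimal_threshold(sweep_df(rev(ctrl), grid, 48),
                          sweep_df(dis[c(2, 3, 1)], grid, 48), "mean")
  expect_equal(o1, o2)
})

test_that("group contrasts reproduce printed-value arithmetic", {
  # two flat curves pinned at given MeanDf values
  grid <- threshold_grid(155, 155, 5)
  flat <- function(v) {
    structure(
      tibble::tibble(gray_level = grid$gray_level, percent = grid$percent,
                     mean_df = v, std_df = 0.01,
                     n_regions = 10L, n_excluded = 0L),
      statistic_cols = c("mean_df", "std_df"),
      class = c("fractal_trajectory", "tbl_df", "tbl", "data.frame")
    )
  }
  opt <- optimal_threshold(flat(1.8593), flat(1.8995), "mean")
  expect_equal(opt$abs_diff, 0.0402)
  expect_equal(opt$percent_change, 2.162, tolerance = 1e-3)

  opt_sd <- optimal_threshold(flat(1), flat(1), "std")
  expect_equal(opt_sd$abs_diff, 0)
})

test_that("df_distribution summarizes pooled regions", {
  imgs <- small_cohort(0.5, 1:2)
  d <- df_distribution(imgs, 90, region_size = 32)
  expect_equal(d$n, 2 * 9)
  expect_equal(d$mean, mean(d$values))
  expect_gt(sum(d$histogram$density > 0), 1)

  # degenerate: every region plane-filling
  dd <- df_distribution(list(matrix(255L, 64, 64)), 10, region_size = 32)
  expect_equal(dd$skewness, 0)
  expect_equal(nrow(dd$histogram), 1)
})

test_that("log-scale distribution excludes non-positive Df with a warning", {
  img <- matrix(0L, 64, 64)
  img[1, 1] <- 255L # one single-pixel region -> Df = 0
  img[33, 1:64] <- 255L
  img[1:64, 33] <- 255L
  expect_warning(
    d <- df_distribution(list(img), 110, region_size = 32, log_scale = TRUE),
    "excluded"
  )
  expect_equal(d$n_excluded, 1)
})
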