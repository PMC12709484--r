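test_that("transform_field applies Dtf with fixed point and pole guard", {
  tf <- transform_field(c(1, 1.8593, 2, 0.5, NA))
  expect_equal(tf$dtf[1], 1) # Df = 1 is the fixed point
  expect_equal(tf$ln_dtf[1], 0)
  expect_equal(tf$dtf[2], 1.8593 / (2 - 1.8593))
  expect_equal(tf$dtf[2], 13.2146, tolerance = 1e-4)
  expect_equal(tf$ln_dtf[2], 2.5815, tolerance = 1e-4)
  expect_true(is.na(tf$dtf[3])) # pole excluded, not clipped
  expect_equal(attr(tf, "n_excluded"), 1)
  expect_error(transform_field(c(2, 2)), "every region excluded")
})

test_that("the transform is monotone and exactly invertible", {
  df <- seq(0.05, 1.95, by = 0.05)
  tf <- transform_field(df)
  expect_true(all(diff(tf$dtf) > 0)) # rank order preserved
  expect_equal(inverse_transform(tf$dtf), df, tolerance = 1e-12)
})

test_that("transform glance reports Mean/STD of lnDtf", {
  field <- df_field(make_pseudo_tissue(96, severity = 0.3, seed = 2), 90,
                    region_size = 32)
  tf <- transform_field(field)
  g <- glance(tf)
  v <- tf$ln_dtf[!is.na(tf$ln_dtf)]
  expect_equal(g$mean_ln_dtf, mean(v))
  expect_equal(g$std_ln_dtf, sd(v))
})

test_that("gaussian_fit scores a true normal high and rejects degenerates", {
  set.seed(11)
  fit <- gaussian_fit(rnorm(10000, 3, 0.5))
  expect_gte(fit$score, 1) # p-value scale: not a systematic rejection
  expect_equal(fit$mean, 3, tolerance = 0.05)
  expect_equal(fit$sd, 0.5, tolerance = 0.05)
  expect_error(gaussian_fit(rep(1, 100)), "degenerate")
  expect_error(gaussian_fit(rnorm(10)), "at least 20")
  expect_error(gaussian_fit(rnorm(100), n_bins = 3), "at least 5 bins")
})

test_that("log transform Gaussianizes lognormal samples", {
  set.seed(21)
  wins <- vapply(1:40, function(i) {
    dtf <- rlnorm(800, meanlog = 2.6, sdlog = 1)
    gaussian_fit(log(dtf))$score > gaussian_fit(dtf)$score
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("sweep_transform mirrors the trajectory machinery on lnDtf", {
  imgs <- small_cohort(0.5, 1:2)
  grid <- threshold_grid(60, 120, 30)
  tr <- sweep_transform(imgs, grid, region_size = 48)
  expect_equal(nrow(tr), 3)
  expect_named(tr, c("gray_level", "percent", "mean_ln_dtf", "std_ln_dtf",
                     "n_regions", "n_excluded"))
  # agreement with a direct df_field + transform at one threshold
  dfs <- unlist(lapply(imgs, function(im) df_field(im, 90, 48)$df))
  dfs <- dfs[!is.na(dfs)]
  keep <- dfs > 0 & dfs < 2 - 1e-9
  ln_ref <- log(dfs[keep] / (2 - dfs[keep]))
  expect_equal(tr$mean_ln_dtf[tr$gray_level == 90], mean(ln_ref))
  expect_equal(tr$std_ln_dtf[tr$gray_level == 90], sd(ln_ref))

  # identical groups: zero contrast at the lowest threshold
  opt <- optimal_threshold(tr, tr, "mean")
  expect_equal(opt$abs_diff, 0)
  expect_equal(opt$gray_level, 60)
})

test_that("variance amplification: lnDtf spreads more than Df near the pole", {
  df <- c(1.88, 1.9, 1.92)
  tf <- transform_field(df)
  # sensitivity factor d lnDtf / d Df = 2 / (Df (2 - Df)) ~ 10 at Df = 1.9
  expect_gt(sd(tf$ln_dtf) / sd(df), 5)
})
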