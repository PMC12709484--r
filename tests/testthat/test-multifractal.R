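test_that("mf_measure normalizes box masses", {
  reg <- matrix(10L, 8, 8)
  m <- mf_measure(reg, 4)
  expect_equal(nrow(m), 4)
  expect_equal(m$p, rep(0.25, 4))
  expect_equal(sum(m$p), 1, tolerance = 1e-12)

  conc <- matrix(0L, 8, 8)
  conc[1:4, 1:4] <- 5L
  m2 <- mf_measure(conc, 4)
  expect_equal(sort(m2$p, decreasing = TRUE), c(1, 0, 0, 0))

  expect_error(mf_measure(matrix(0L, 4, 4), 2), "all-zero")
})

test_that("cascade box masses are exact weight products", {
  w <- c(0.4, 0.3, 0.2, 0.1)
  m <- make_cascade(weights = w, levels = 5)
  # level-1 quadrant masses are the weights themselves
  q <- mf_measure(m, nrow(m) / 2)
  expect_equal(sort(q$p), sort(w), tolerance = 1e-12)
  # finest boxes are products of 5 weights
  expect_equal(max(m), 0.4^5, tolerance = 1e-15)
  expect_equal(min(m), 0.1^5, tolerance = 1e-15)
})

test_that("mu_weights matches direct arithmetic and handles extremes", {
  expect_equal(as.vector(mu_weights(rep(0.25, 4), 0)), rep(0.25, 4))
  p <- c(0.5, 0.3, 0.2)
  expect_equal(as.vector(mu_weights(p, 1)), p)
  mu <- mu_weights(c(0.9, 0.1), 10)
  expect_equal(as.vector(mu), c(0.9^10, 0.1^10) / (0.9^10 + 0.1^10))
  # zero-mass boxes dropped before exponentiation
  mu2 <- mu_weights(c(0.7, 0, 0.3), -10)
  expect_equal(length(mu2), 2)
  expect_equal(sum(mu2), 1)
  # log-space stability at extreme Q and tiny masses
  mu3 <- mu_weights(c(1e-200, 1 - 1e-200), -50)
  expect_false(anyNA(mu3))
  expect_equal(sum(mu3), 1)
})

test_that("a constant region is the monofractal limit", {
  sp <- mf_spectrum(matrix(100L, 64, 64), q_grid = seq(-10, 10, 2),
                    eps_list = c(2, 4, 8, 16))
  expect_equal(sp$alpha, rep(2, nrow(sp)), tolerance = 1e-9)
  expect_equal(sp$f_alpha, rep(2, nrow(sp)), tolerance = 1e-9)
  expect_equal(spectrum_params(sp)$delta_alpha, 0, tolerance = 1e-9)
})

test_that("cascade spectrum matches the closed form across Q", {
  w <- c(0.4, 0.3, 0.2, 0.1)
  m <- make_cascade(weights = w, levels = 6)
  sp <- mf_spectrum(m, eps_list = c(2, 4, 8, 16))
  an <- cascade_spectrum(w, sp$q)
  expect_true(max(abs(sp$alpha - an$alpha)) < 0.02)
  expect_true(max(abs(sp$f_alpha - an$f_alpha)) < 0.02)
  # extreme-Q limits approach the weight-set endpoints
  expect_equal(sp$alpha[sp$q == 10], -log2(0.4), tolerance = 0.05)
  expect_equal(sp$alpha[sp$q == -10], -log2(0.1), tolerance = 0.05)
  # mass conservation of mu at every Q and eps is implicit in the estimator;
  # spot-check the normalization invariant
  for (e in c(2, 8)) {
    p <- mf_measure(m, e)$p
    for (q in c(-10, 0, 3.5)) expect_equal(sum(mu_weights(p, q)), 1,
                                           tolerance = 1e-12)
  }
})

test_that("spectrum is arrangement-invariant for exact cascades", {
  w <- c(0.4, 0.3, 0.2, 0.1)
  plain <- mf_spectrum(make_cascade(w, levels = 5),
                       q_grid = seq(-6, 6, 2), eps_list = c(2, 4, 8))
  shuf <- mf_spectrum(make_cascade(w, levels = 5, shuffle = TRUE, seed = 1),
                      q_grid = seq(-6, 6, 2), eps_list = c(2, 4, 8))
  expect_equal(shuf$alpha, plain$alpha, tolerance = 1e-9)
  expect_equal(shuf$f_alpha, plain$f_alpha, tolerance = 1e-9)
})

test_that("f(Q) is maximal near Q = 0 and bandwidth grows with disparity", {
  # increasing top-weight disparity at fixed smallest weight
  weight_sets <- list(c(0.25, 0.25, 0.25, 0.25),
                      c(0.4, 0.3, 0.2, 0.1),
                      c(0.55, 0.2, 0.15, 0.1),
                      c(0.7, 0.1, 0.1, 0.1))
  widths <- vapply(weight_sets, function(w) {
    sp <- mf_spectrum(make_cascade(w, levels = 6), eps_list = c(2, 4, 8, 16))
    expect_lte(max(sp$f_alpha), sp$f_alpha[sp$q == 0] + 1e-6)
    spectrum_params(sp)$delta_alpha
  }, numeric(1))
  expect_true(all(diff(widths) > 0)) # strictly broader with disparity
})

test_that("spectrum parameter arithmetic reproduces the extrema", {
  sp <- mf_spectrum(make_cascade(levels = 4), q_grid = seq(-4, 4, 1),
                    eps_list = c(2, 4, 8))
  pars <- spectrum_params(sp)
  expect_equal(pars$delta_alpha, pars$alpha_max - pars$alpha_min)
  expect_equal(pars$delta_f, pars$f_max - pars$f_min)
  expect_gte(pars$delta_alpha, 0)
  one <- spectrum_params(sp[3, ])
  expect_equal(one$delta_alpha, 0)
  expect_equal(one$delta_f, 0)
})

test_that("single-scale fallback warns and group spectra average pointwise", {
  m <- make_cascade(levels = 4)
  expect_warning(sp <- mf_spectrum(m, q_grid = c(0, 2), eps_list = 4),
                 "single")
  expect_equal(nrow(sp), 2)
  g <- group_spectrum(list(m, m), q_grid = seq(-2, 2, 1),
                      eps_list = c(2, 4, 8))
  solo <- mf_spectrum(m, q_grid = seq(-2, 2, 1), eps_list = c(2, 4, 8))
  expect_equal(g$alpha, solo$alpha)
})
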