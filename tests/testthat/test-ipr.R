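test_that("build_lattice derives relative-fluctuation potentials", {
  w <- matrix(c(100, 100, 100, 300), 2, 2)
  lat <- build_lattice(w)
  expect_equal(as.vector(lat$eps), c(-1 / 3, -1 / 3, -1 / 3, 1))
  expect_equal(lat$t, 1)
  # scale invariance of dI / I0
  expect_equal(build_lattice(2 * w)$eps, lat$eps)
  # constant window: ordered lattice
  expect_true(all(build_lattice(matrix(7, 3, 3))$eps == 0))
  expect_error(build_lattice(matrix(0, 2, 2)), "positive")
  expect_error(build_lattice(matrix(1, 2, 3)), "square")
})

test_that("ordered-lattice spectra match closed forms", {
  # L = 2, eps = 0: the 4-cycle, eigenvalues {-2, 0, 0, 2}
  h2 <- hamiltonian(make_anderson(2, 0))
  expect_equal(h2, t(h2))
  expect_equal(eigen(h2, symmetric = TRUE, only.values = TRUE)$values,
               c(2, 0, 0, -2), tolerance = 1e-12)
  # L = 3 open chain modes: tensor sums of 2 cos(k pi / 4)
  h3 <- hamiltonian(make_anderson(3, 0))
  path3 <- 2 * cos((1:3) * pi / 4)
  expected <- sort(as.vector(outer(path3, path3, "+")))
  expect_equal(sort(eigen(h3, symmetric = TRUE, only.values = TRUE)$values),
               expected, tolerance = 1e-12)
})

test_that("IPR bounds and normalization identities hold", {
  res <- ipr_of_lattice(make_anderson(8, 5, seed = 2))
  n <- 8^2
  expect_true(all(res$ipr >= 1 / n - 1e-12))
  expect_true(all(res$ipr <= 1 + 1e-12))
  expect_gte(res$mean_ipr, 1 / n)
  # a uniform eigenvector would have IPR exactly 1/N
  expect_equal(sum(rep(1 / sqrt(n), n)^4), 1 / n)
})

test_that("uniform potential shifts leave every IPR unchanged", {
  lat <- make_anderson(6, 3, seed = 4)
  shifted <- tissuefractal:::new_lattice(6, lat$eps + 7.5)
  expect_equal(sort(ipr_of_lattice(shifted)$ipr),
               sort(ipr_of_lattice(lat)$ipr), tolerance = 1e-9)
})

test_that("mean IPR grows with Anderson disorder width", {
  set.seed(0)
  mean_at <- function(w, seeds) {
    mean(vapply(seeds, function(s) {
      ipr_of_lattice(make_anderson(12, w, seed = s))$mean_ipr
    }, numeric(1)))
  }
  seeds <- 1:40
  means <- vapply(c(0.5, 2, 5, 10), mean_at, numeric(1), seeds = seeds)
  expect_true(all(diff(means) > 0))
  # ordered lattice sits below every disordered mean
  expect_lt(ipr_of_lattice(make_anderson(12, 0))$mean_ipr, means[1])
})

test_that("ipr_scan tiles windows, skips dark windows, aggregates", {
  img <- matrix(100L, 16, 16)
  scan <- ipr_scan(img, sizes = c(4, 8))
  expect_equal(sum(scan$l == 4), 16)
  expect_equal(sum(scan$l == 8), 4)
  g <- glance(scan)
  expect_equal(g$std_ipr, c(0, 0), tolerance = 1e-12) # constant image

  dark <- img
  dark[1:4, 1:4] <- 0L
  s2 <- ipr_scan(dark, sizes = 4)
  expect_equal(sum(is.na(s2$mean_ipr)), 1)
  expect_equal(glance(s2)$n_windows, 15)

  expect_warning(ipr_scan(matrix(50L, 4, 4), sizes = c(4, 8)), "skipped")
})

test_that("ipr_map rasterizes window values back onto the pixel grid", {
  img <- make_pseudo_tissue(24, severity = 0.5, seed = 3)
  scan <- ipr_scan(img, sizes = 8)
  m <- ipr_map(scan, image = 1, l = 8)
  expect_equal(dim(m), c(24, 24))
  expect_equal(m[1, 1], scan$mean_ipr[scan$row == 1 & scan$col == 1][1])
  expect_equal(length(unique(as.vector(m))), 9)
})
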