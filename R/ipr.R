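#' Intensity-derived tight-binding optical lattice
#'
#' Maps a square image window onto a disordered optical lattice: each pixel
#' becomes a site whose potential is the relative intensity fluctuation
#' `eps_i = (I_i - Ibar) / Ibar` about the window mean, in units of the
#' hopping amplitude `t = 1`. Refractive-index fluctuations track relative
#' intensity fluctuations, so the potential is invariant under a uniform
#' intensity rescaling. An optional `disorder_scale` multiplies the
#' potential, since the physical proportionality constant between relative
#' intensity and refractive-index fluctuation is sample-dependent.
#'
#' @param window Square numeric matrix (side >= 2) with positive mean.
#' @param disorder_scale Multiplier applied to the potentials.
#' @return An `optical_lattice` list: `l` (sites per side), `eps` (L x L
#'   potential matrix), `t` (hopping, fixed 1).
#' @examples
#' build_lattice(matrix(c(100, 100, 100, 300), 2, 2))$eps
#' @export
build_lattice <- function(window, disorder_scale = 1) {
  stopifnot(is.matrix(window))
  l <- nrow(window)
  if (ncol(window) != l || l < 2) {
    stop("window must be square with side >= 2", call. = FALSE)
  }
  ibar <- mean(window)
  if (ibar <= 0) {
    stop("window mean intensity must be positive", call. = FALSE)
  }
  new_lattice(l, disorder_scale * (window - ibar) / ibar)
}

new_lattice <- function(l, eps) {
  stopifnot(all(is.finite(eps)))
  structure(list(l = as.integer(l), eps = eps, t = 1),
            class = "optical_lattice")
}

#' @export
print.optical_lattice <- function(x, ...) {
  cat(sprintf("Tight-binding lattice: %d x %d sites, potential sd = %.4f\n",
              x$l, x$l, stats::sd(x$eps)))
  invisible(x)
}

#' Tight-binding Hamiltonian of an optical lattice
#'
#' Builds the dense symmetric `L^2 x L^2` operator with the site potentials
#' on the diagonal and hopping `t` between 4-neighbour sites of the square
#' grid, open (hard-wall) boundaries by default. Sites are numbered
#' column-major, matching R's matrix vectorization.
#'
#' @param lattice An `optical_lattice` from [build_lattice()] or
#'   [make_anderson()].
#' @param periodic If `TRUE`, wrap the lattice on a torus instead of hard
#'   walls.
#' @return A symmetric numeric matrix.
#' @export
hamiltonian <- function(lattice, periodic = FALSE) {
  l <- lattice$l
  n <- l * l
  h <- matrix(0, n, n)
  diag(h) <- as.vector(lattice$eps)
  idx <- function(i, j) (j - 1L) * l + i
  for (j in seq_len(l)) {
    for (i in seq_len(l)) {
      a <- idx(i, j)
      if (i < l) h[a, idx(i + 1L, j)] <- h[idx(i + 1L, j), a] <- lattice$t
      if (j < l) h[a, idx(i, j + 1L)] <- h[idx(i, j + 1L), a] <- lattice$t
      if (periodic && i == l && l > 2) {
        h[a, idx(1L, j)] <- h[idx(1L, j), a] <- lattice$t
      }
      if (periodic && j == l && l > 2) {
        h[a, idx(i, 1L)] <- h[idx(i, 1L), a] <- lattice$t
      }
    }
  }
  h
}

#' Inverse participation ratios of all lattice eigenstates
#'
#' Diagonalizes the tight-binding Hamiltonian and computes, for each
#' unit-normalized eigenfunction, `IPR_k = sum(E_k(site)^4)`: 1/L^2 for a
#' fully extended state, 1 for a state localized on a single site. The
#' mean over all L^2 eigenstates quantifies the lattice's structural
#' disorder.
#'
#' @param lattice An `optical_lattice`.
#' @param periodic Boundary condition, as in [hamiltonian()].
#' @return An `ipr_result` list: `ipr` (per-eigenstate values, ascending
#'   eigenvalue order), `mean_ipr`, `l`, `degenerate` (flag: numerically
#'   degenerate eigenvalues detected, where eigenvector mixing within the
#'   degenerate subspace makes individual IPRs basis-dependent).
#' @export
ipr_of_lattice <- function(lattice, periodic = FALSE) {
  h <- hamiltonian(lattice, periodic)
  es <- eigen(h, symmetric = TRUE)
  vec <- es$vectors
  ipr <- colSums(vec^4)
  gaps <- abs(diff(es$values))
  structure(
    list(ipr = ipr, mean_ipr = mean(ipr), l = lattice$l,
         eigenvalues = es$values,
         degenerate = any(gaps < 1e-10)),
    class = "ipr_result"
  )
}

#' Mean IPR of one image window
#'
#' Convenience wrapper: builds the optical lattice of a window and returns
#' its mean inverse participation ratio.
#'
#' @inheritParams build_lattice
#' @param periodic Boundary condition.
#' @return The mean IPR (a scalar in `[1/L^2, 1]`).
#' @export
ipr_of_window <- function(window, disorder_scale = 1, periodic = FALSE) {
  ipr_of_lattice(build_lattice(window, disorder_scale), periodic)$mean_ipr
}

#' IPR scan over window (pixel) sizes
#'
#' Tiles each image into non-overlapping `L x L` windows for every requested
#' size, computes each window's mean IPR, and pools windows across images.
#' In media with spatially correlated heterogeneity the pooled mean IPR
#' grows with window size: larger eigenfunctions sample larger mass-density
#' fluctuations. Sizes exceeding an image's smaller side are skipped with a
#' warning.
#'
#' @param images List of grayscale matrices (one group), or a single matrix.
#' @param sizes Window sides in pixels; default `c(2, 4, 8, 16, 32)`.
#' @param disorder_scale,periodic Passed to [build_lattice()] /
#'   [hamiltonian()].
#' @return An `ipr_scan` tibble with one row per window: `l`, `image`,
#'   `row`, `col`, `mean_ipr`. [glance()] aggregates to per-size group
#'   mean and sample standard deviation across windows.
#' @examples
#' img <- make_pseudo_tissue(size = 32, seed = 1)
#' glance(ipr_scan(img, sizes = c(4, 8)))
#' @export
ipr_scan <- function(images, sizes = c(2, 4, 8, 16, 32),
                     disorder_scale = 1, periodic = FALSE) {
  images <- as_image_list(images)
  out <- purrr::map_dfr(sort(unique(as.integer(sizes))), function(l) {
    purrr::imap_dfr(images, function(img, k) {
      if (min(dim(img)) < l) {
        warning("image ", k, " smaller than window size ", l, "; skipped")
        return(tibble::tibble())
      }
      tiles <- tile(img, l)
      tibble::tibble(
        l = l, image = k, row = tiles$row, col = tiles$col,
        mean_ipr = purrr::map_dbl(tiles$tile, function(w) {
          # all-dark windows carry no optical medium: no lattice, no IPR
          if (mean(w) <= 0) NA_real_
          else ipr_of_window(w, disorder_scale, periodic)
        })
      )
    })
  })
  structure(out, n_skipped = sum(is.na(out$mean_ipr)),
            class = c("ipr_scan", class(out)))
}

#' @exportS3Method generics::glance
glance.ipr_scan <- function(x, ...) {
  dat <- dplyr::filter(tibble::as_tibble(x), !is.na(mean_ipr))
  out <- dplyr::summarise(
    dplyr::group_by(dat, l),
    group_mean = mean(mean_ipr),
    group_std = stats::sd(mean_ipr),
    n_windows = dplyr::n(),
    .groups = "drop"
  )
  dplyr::rename(out, mean_ipr = group_mean, std_ipr = group_std)
}

#' Rasterize per-window IPR values into a colormap matrix
#'
#' Expands the per-window mean IPR values of one image and one window size
#' back onto the pixel grid, yielding an image-shaped matrix suitable for a
#' heatmap of local disorder.
#'
#' @param scan An [ipr_scan()] tibble.
#' @param image Image index within the scan.
#' @param l Window size to rasterize.
#' @return A numeric matrix (window grid upsampled by `l`).
#' @export
ipr_map <- function(scan, image = 1, l = max(scan$l)) {
  sub <- dplyr::filter(tibble::as_tibble(scan), .data$image == !!image,
                       .data$l == !!l)
  if (nrow(sub) == 0) {
    stop("no windows for that image/size", call. = FALSE)
  }
  grid <- matrix(NA_real_, max(sub$row), max(sub$col))
  grid[cbind(sub$row, sub$col)] <- sub$mean_ipr
  grid[rep(seq_len(nrow(grid)), each = l),
       rep(seq_len(ncol(grid)), each = l)]
}
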