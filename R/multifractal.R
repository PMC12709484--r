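#' Normalized box-mass measure of a grayscale region
#'
#' Partitions the region into boxes of side `eps` (top-left anchored, ragged
#' edge boxes included) and returns each box's share of the total pixel
#' intensity — the probability measure underlying the direct multifractal
#' spectrum estimator.
#'
#' @param region Non-negative numeric matrix (grayscale intensities or a raw
#'   cascade measure).
#' @param eps Box side in pixels.
#' @return A tibble with `box_row`, `box_col`, `p` (mass fractions summing
#'   to 1); attribute `eps`.
#' @export
mf_measure <- function(region, eps) {
  stopifnot(is.matrix(region), eps >= 1)
  if (anyNA(region) || min(region) < 0) {
    stop("region must be non-negative", call. = FALSE)
  }
  total <- sum(region)
  if (total <= 0) {
    stop("all-zero region: measure undefined", call. = FALSE)
  }
  eps <- as.integer(eps)
  gi <- (seq_len(nrow(region)) - 1L) %/% eps
  gj <- (seq_len(ncol(region)) - 1L) %/% eps
  band <- rowsum(region, gi, reorder = FALSE)
  block <- t(rowsum(t(band), gj, reorder = FALSE))
  out <- tibble::tibble(
    box_row = as.vector(row(block)),
    box_col = as.vector(col(block)),
    p = as.vector(block) / total
  )
  attr(out, "eps") <- eps
  out
}

#' Q-warped box weights
#'
#' Computes `mu_i = p_i^Q / sum(p_i^Q)` over the occupied boxes, in
#' log-space for numerical stability at large |Q|. Zero-mass boxes are
#' dropped before exponentiation (`0^Q` diverges for negative Q).
#'
#' @param p Numeric vector of box mass fractions (the `p` column of
#'   [mf_measure()]).
#' @param q Single finite moment order.
#' @return Numeric vector of weights over the occupied boxes, summing to 1;
#'   attribute `occupied` holds the indices of the retained boxes.
#' @export
mu_weights <- function(p, q) {
  stopifnot(is.finite(q))
  occupied <- which(p > 0)
  if (length(occupied) == 0L) {
    stop("no occupied boxes", call. = FALSE)
  }
  lw <- q * log(p[occupied])
  lw <- lw - max(lw)
  mu <- exp(lw)
  mu <- mu / sum(mu)
  attr(mu, "occupied") <- occupied
  mu
}

#' Direct multifractal spectrum of a grayscale region
#'
#' Estimates the singularity spectrum f(alpha) versus alpha by the direct
#' (mu-measure) method: for each moment order Q, `alpha(Q)` is the slope of
#' `sum(mu_i * ln p_i)` versus `ln eps` and `f(Q)` the slope of
#' `sum(mu_i * ln mu_i)` versus `ln eps`, least-squares over the supplied
#' box sides. Positive Q probes the densest boxes, negative Q the most
#' rarefied ones; a monofractal (e.g. a constant region) collapses to the
#' single point alpha = f = 2.
#'
#' @param region Non-negative numeric matrix.
#' @param q_grid Moment orders; default -10 to 10 in steps of 0.5.
#' @param eps_list At least two box sides; default `c(2, 4, 6, 10, 12)`,
#'   mirroring the box-counting scales on 60 x 60 regions. With a single
#'   side the estimator falls back to the single-scale quotient
#'   (sum / ln eps) with a warning.
#' @return An `mf_spectrum` tibble: `q`, `alpha`, `f_alpha`, `r2_alpha`,
#'   `r2_f`.
#' @examples
#' m <- make_cascade(weights = c(0.4, 0.3, 0.2, 0.1), levels = 6)
#' sp <- mf_spectrum(m, eps_list = c(2, 4, 8, 16))
#' spectrum_params(sp)
#' @export
mf_spectrum <- function(region, q_grid = seq(-10, 10, by = 0.5),
                        eps_list = c(2, 4, 6, 10, 12)) {
  eps_list <- sort(unique(as.integer(eps_list)))
  single_eps <- length(eps_list) == 1L
  if (single_eps) {
    warning("single box side: falling back to the single-scale quotient")
  }
  measures <- purrr::map(eps_list, function(e) mf_measure(region, e)$p)
  log_eps <- log(eps_list)
  out <- purrr::map_dfr(q_grid, function(q) {
    sums <- purrr::map_dfr(measures, function(p) {
      mu <- mu_weights(p, q)
      pk <- p[attr(mu, "occupied")]
      tibble::tibble(num_alpha = sum(mu * log(pk)),
                     num_f = sum(mu * log(mu)))
    })
    if (single_eps) {
      tibble::tibble(q = q,
                     alpha = sums$num_alpha / log_eps,
                     f_alpha = sums$num_f / log_eps,
                     r2_alpha = NA_real_, r2_f = NA_real_)
    } else {
      fa <- ols_slope(log_eps, sums$num_alpha)
      ff <- ols_slope(log_eps, sums$num_f)
      tibble::tibble(q = q, alpha = fa$slope, f_alpha = ff$slope,
                     r2_alpha = fa$r2, r2_f = ff$r2)
    }
  })
  structure(out,
            eps_list = eps_list,
            class = c("mf_spectrum", class(out)))
}

#' Summary parameters of a multifractal spectrum
#'
#' Extracts the spectrum extrema over the Q grid: the singularity exponents
#' `alpha_min`/`alpha_max` and bandwidth `delta_alpha = alpha_max -
#' alpha_min`, and the spectrum heights `f_min`/`f_max` with `delta_f`.
#' A wide bandwidth signals a heterogeneous (multifractal) intensity
#' distribution; a point spectrum a monofractal. Estimated `f` exceeding
#' the support dimension (2 for planar images) is reported as-is and
#' flagged via the `f_exceeds_dimension` column, never clamped.
#'
#' @param spectrum An [mf_spectrum()] tibble (>= 1 Q point).
#' @return A one-row tibble: `alpha_min`, `alpha_max`, `delta_alpha`,
#'   `f_min`, `f_max`, `delta_f`, `f_exceeds_dimension`.
#' @export
spectrum_params <- function(spectrum) {
  stopifnot(nrow(spectrum) >= 1)
  tibble::tibble(
    alpha_min = min(spectrum$alpha),
    alpha_max = max(spectrum$alpha),
    delta_alpha = max(spectrum$alpha) - min(spectrum$alpha),
    f_min = min(spectrum$f_alpha),
    f_max = max(spectrum$f_alpha),
    delta_f = max(spectrum$f_alpha) - min(spectrum$f_alpha),
    f_exceeds_dimension = any(spectrum$f_alpha > 2 + 1e-9)
  )
}

#' Group-average multifractal spectrum
#'
#' Pointwise mean over the Q grid of the per-image spectra of a group.
#'
#' @param images List of grayscale matrices.
#' @param q_grid,eps_list As in [mf_spectrum()].
#' @return An `mf_spectrum` tibble of the averaged `alpha(Q)` and `f(Q)`.
#' @export
group_spectrum <- function(images, q_grid = seq(-10, 10, by = 0.5),
                           eps_list = c(2, 4, 6, 10, 12)) {
  images <- as_image_list(images)
  specs <- purrr::map(images, mf_spectrum, q_grid = q_grid,
                      eps_list = eps_list)
  out <- tibble::tibble(
    q = q_grid,
    alpha = rowMeans(sapply(specs, function(s) s$alpha)),
    f_alpha = rowMeans(sapply(specs, function(s) s$f_alpha)),
    r2_alpha = rowMeans(sapply(specs, function(s) s$r2_alpha)),
    r2_f = rowMeans(sapply(specs, function(s) s$r2_f))
  )
  structure(out,
            eps_list = sort(unique(as.integer(eps_list))),
            n_images = length(images),
            class = c("mf_spectrum", class(out)))
}
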