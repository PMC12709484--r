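#' Functional transformation of the fractal dimension
#'
#' Maps each region's fractal dimension through `Dtf = Df / (Dfmax - Df)`
#' with `Dfmax = 2` for planar images, and takes the natural logarithm. The
#' map is strictly increasing on (0, 2), so region rank-order is preserved,
#' and it stretches the upper tail near the plane-filling limit: long-tailed
#' Df distributions become approximately Gaussian in ln Dtf. Regions within
#' `delta` of the Dfmax pole, or with Df <= 0, are excluded (not clipped —
#' clipping would manufacture outliers in ln Dtf) and counted.
#'
#' @param field A [df_field()] tibble, or a plain numeric vector of Df
#'   values.
#' @param df_max Pole of the transformation; 2 for 2D micrographs.
#' @param delta Pole guard: regions with `Df >= df_max - delta` are
#'   excluded.
#' @return A `transformed_sample` tibble with columns of `field` plus `dtf`
#'   and `ln_dtf` (`NA` where excluded); attributes `df_max` and
#'   `n_excluded`. [glance()] gives Mean(lnDtf) / STD(lnDtf).
#' @examples
#' transform_field(c(1, 1.8593))$dtf # 1, 13.215
#' @export
transform_field <- function(field, df_max = 2, delta = 1e-9) {
  if (is.numeric(field) && !is.matrix(field)) {
    field <- tibble::tibble(df = field)
  }
  stopifnot("df" %in% names(field))
  df <- field$df
  bad <- is.na(df) | df <= 0 | df >= df_max - delta
  dtf <- ifelse(bad, NA_real_, df / (df_max - df))
  out <- dplyr::mutate(tibble::as_tibble(field), dtf = dtf,
                       ln_dtf = log(dtf))
  if (all(is.na(out$dtf))) {
    stop("every region excluded by the pole/positivity guard", call. = FALSE)
  }
  structure(out,
            df_max = df_max,
            n_excluded = sum(bad & !is.na(df)),
            gray_level = attr(field, "gray_level"),
            percent = attr(field, "percent"),
            class = c("transformed_sample", class(out)))
}

#' Invert the fractal functional transformation
#'
#' @param dtf Transformed values.
#' @param df_max Pole used in the forward map.
#' @return `Df = df_max * dtf / (1 + dtf)`.
#' @export
inverse_transform <- function(dtf, df_max = 2) {
  df_max * dtf / (1 + dtf)
}

#' @exportS3Method generics::glance
glance.transformed_sample <- function(x, ...) {
  v <- x$ln_dtf[!is.na(x$ln_dtf)]
  tibble::tibble(
    mean_ln_dtf = mean(v),
    std_ln_dtf = if (length(v) > 1) stats::sd(v) else NA_real_,
    n_regions = length(v),
    n_excluded = attr(x, "n_excluded")
  )
}

#' Chi-square Gaussianity score of a sample
#'
#' Fits a normal by moments and computes a Pearson chi-square
#' goodness-of-fit statistic on bins of equal expected probability under
#' the fitted normal (`n_bins - 3` degrees of freedom: bins minus one,
#' minus the two estimated moments). The Gaussianity score is 100 times the
#' chi-square p-value, so a well-fitting Gaussian scores high (scores above
#' 90 indicate no detectable departure at the 0.1 level).
#'
#' @param x Numeric vector (>= 20 values), or a `transformed_sample` (its
#'   `ln_dtf` column is used).
#' @param n_bins Number of equal-probability bins (>= 5).
#' @return A one-row `gaussian_fit` tibble: `mean`, `sd`, `chisq`,
#'   `df`, `p_value`, `score`, `n`, `n_bins`.
#' @examples
#' set.seed(1)
#' gaussian_fit(rnorm(1000))$score
#' @export
gaussian_fit <- function(x, n_bins = 10) {
  if (inherits(x, "transformed_sample")) x <- x$ln_dtf
  x <- x[!is.na(x)]
  if (length(x) < 20) {
    stop("need at least 20 values for the chi-square fit", call. = FALSE)
  }
  if (n_bins < 5) {
    stop("need at least 5 bins", call. = FALSE)
  }
  m <- mean(x)
  s <- stats::sd(x)
  if (s < 1e-12) {
    stop("degenerate (zero-variance) sample", call. = FALSE)
  }
  breaks <- stats::qnorm(seq(0, 1, length.out = n_bins + 1), m, s)
  breaks[1] <- -Inf
  breaks[n_bins + 1] <- Inf
  observed <- as.vector(table(cut(x, breaks)))
  expected <- length(x) / n_bins
  chisq <- sum((observed - expected)^2 / expected)
  dof <- n_bins - 3
  p <- stats::pchisq(chisq, dof, lower.tail = FALSE)
  tibble::new_tibble(
    tibble::tibble(mean = m, sd = s, chisq = chisq, df = dof,
                   p_value = p, score = 100 * p,
                   n = length(x), n_bins = as.integer(n_bins)),
    class = "gaussian_fit"
  )
}

#' Threshold sweep of the transformed-fractal statistics
#'
#' The threshold-trajectory machinery of [sweep_df()] applied to ln Dtf:
#' at each threshold the per-region fractal dimensions of all images are
#' pooled, transformed, and aggregated into Mean(lnDtf) and STD(lnDtf).
#' Regions excluded by the pole guard are dropped from the aggregates and
#' counted.
#'
#' @inheritParams sweep_df
#' @param df_max,delta Passed to the transformation.
#' @return A `transform_trajectory` tibble: `gray_level`, `percent`,
#'   `mean_ln_dtf`, `std_ln_dtf`, `n_regions`, `n_excluded`.
#' @export
sweep_transform <- function(images, grid = threshold_grid(),
                            region_size = 60,
                            box_sizes = c(2, 4, 6, 10, 12),
                            df_max = 2, delta = 1e-9, group_label = NULL) {
  value_fun <- function(df) {
    keep <- df > 0 & df < df_max - delta
    log(df[keep] / (df_max - df[keep]))
  }
  out <- sweep_statistic(images, grid, region_size, box_sizes, value_fun)
  out <- dplyr::rename(out, mean_ln_dtf = mean_value, std_ln_dtf = std_value)
  structure(out,
            statistic_cols = c("mean_ln_dtf", "std_ln_dtf"),
            group_label = group_label,
            region_size = as.integer(region_size),
            class = c("transform_trajectory", class(out)))
}
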