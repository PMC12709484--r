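#' Sweep binarization thresholds to trace a fractal-dimension trajectory
#'
#' For every threshold in the grid, computes the per-region fractal dimension
#' of every image and pools the regions across images into MeanDf and STDDf.
#' Thresholds at which every region of every image is empty stay in the
#' curve as `NA` gaps rather than zeros — zeros would fabricate a spurious
#' optimum when contrasting groups.
#'
#' @param images A list of grayscale matrices (one group), or a single
#'   matrix.
#' @param grid Threshold grid tibble from [threshold_grid()].
#' @param region_size,box_sizes Passed to [df_field()].
#' @param group_label Optional label stored on the result.
#' @return A `fractal_trajectory` tibble: one row per threshold with
#'   `gray_level`, `percent`, `mean_df`, `std_df`, `n_regions`,
#'   `n_excluded`.
#' @examples
#' imgs <- list(make_pseudo_tissue(size = 120, seed = 1))
#' sweep_df(imgs, threshold_grid(60, 120, 30), region_size = 30)
#' @export
sweep_df <- function(images, grid = threshold_grid(), region_size = 60,
                     box_sizes = c(2, 4, 6, 10, 12), group_label = NULL) {
  out <- sweep_statistic(images, grid, region_size, box_sizes,
                         value_fun = identity)
  out <- dplyr::rename(out, mean_df = mean_value, std_df = std_value)
  structure(out,
            statistic_cols = c("mean_df", "std_df"),
            group_label = group_label,
            region_size = as.integer(region_size),
            class = c("fractal_trajectory", class(out)))
}

# Shared sweep engine: pools per-region Df across images at each threshold,
# maps Df -> value via value_fun (identity for Df, ln Dtf for the transform),
# and aggregates mean/sd. value_fun may drop elements (returns a vector of
# retained values).
sweep_statistic <- function(images, grid, region_size, box_sizes, value_fun) {
  images <- as_image_list(images)
  stopifnot(nrow(grid) >= 1)
  purrr::pmap_dfr(grid, function(gray_level, percent) {
    dfs <- purrr::map(images, function(img) {
      tryCatch(df_field(img, gray_level, region_size, box_sizes)$df,
               error = function(e) numeric(0))
    })
    pooled <- unlist(dfs)
    n_excluded <- sum(is.na(pooled))
    pooled <- pooled[!is.na(pooled)]
    values <- value_fun(pooled)
    tibble::tibble(
      gray_level = gray_level,
      percent = percent,
      mean_value = if (length(values)) mean(values) else NA_real_,
      std_value = if (length(values) > 1) stats::sd(values) else NA_real_,
      n_regions = length(values),
      n_excluded = n_excluded + (length(pooled) - length(values))
    )
  })
}

as_image_list <- function(images) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1, all(vapply(images, is.matrix, logical(1))))
  images
}

#' Optimal threshold maximizing a between-group contrast
#'
#' Scans two trajectories over a common threshold grid and returns the
#' threshold at which the absolute difference of the chosen statistic is
#' maximal, together with the group values, their absolute difference, and
#' the percent change relative to the first (control) group. Ties are broken
#' towards the lowest threshold; entries undefined in either curve are
#' skipped.
#'
#' @param control,disease Trajectory tibbles over identical grids
#'   ([sweep_df()] or [sweep_transform()]).
#' @param statistic `"mean"` or `"std"` — which curve to contrast.
#' @return A one-row tibble: `gray_level`, `percent`, `value_control`,
#'   `value_disease`, `abs_diff`, `percent_change`.
#' @export
optimal_threshold <- function(control, disease, statistic = c("mean", "std")) {
  statistic <- match.arg(statistic)
  if (!identical(control$gray_level, disease$gray_level)) {
    stop("trajectories must share an identical threshold grid", call. = FALSE)
  }
  col <- grep(paste0("^", statistic, "_"), names(control), value = TRUE)[1]
  a <- control[[col]]
  b <- disease[[col]]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) {
    stop("no threshold has the statistic defined in both groups",
         call. = FALSE)
  }
  diff <- abs(b - a)
  diff[!ok] <- -Inf
  k <- which.max(diff) # which.max returns the first (lowest) maximiser
  tibble::tibble(
    gray_level = control$gray_level[k],
    percent = control$percent[k],
    value_control = a[k],
    value_disease = b[k],
    abs_diff = abs(b[k] - a[k]),
    percent_change = 100 * (b[k] - a[k]) / a[k]
  )
}

#' Pooled distribution of per-region fractal dimensions
#'
#' Pools the per-region Df (or ln Df) values of an image set at one
#' threshold and summarizes the distribution: normalized histogram, mean,
#' standard deviation and skewness. On the log scale, regions with Df <= 0
#' are excluded (with a warning) since the logarithm is undefined there.
#'
#' @param images List of grayscale matrices.
#' @param gray_level Binarization threshold.
#' @param region_size,box_sizes Passed to [df_field()].
#' @param log_scale If `TRUE`, summarize ln Df instead of Df.
#' @param n_bins Number of histogram bins.
#' @return A list of class `df_distribution`: `values`, `histogram` (tibble
#'   with `mid`, `density`), `mean`, `std`, `skewness`, `n`, `n_excluded`.
#' @export
df_distribution <- function(images, gray_level, region_size = 60,
                            box_sizes = c(2, 4, 6, 10, 12),
                            log_scale = FALSE, n_bins = 20) {
  images <- as_image_list(images)
  values <- unlist(purrr::map(images, function(img) {
    tryCatch(df_field(img, gray_level, region_size, box_sizes)$df,
             error = function(e) numeric(0))
  }))
  values <- values[!is.na(values)]
  n_excluded <- 0L
  if (log_scale) {
    bad <- values <= 0
    if (any(bad)) {
      warning(sum(bad), " region(s) with Df <= 0 excluded from log scale")
      n_excluded <- sum(bad)
      values <- values[!bad]
    }
    values <- log(values)
  }
  if (length(values) < 2) {
    stop("need at least two defined region values", call. = FALSE)
  }
  if (diff(range(values)) < 1e-12) {
    histogram <- tibble::tibble(mid = mean(values), density = 1)
    skew <- 0
  } else {
    h <- graphics::hist(values, breaks = n_bins, plot = FALSE)
    histogram <- tibble::tibble(mid = h$mids, density = h$density)
    s <- stats::sd(values)
    skew <- mean((values - mean(values))^3) / s^3
  }
  structure(
    list(values = values, histogram = histogram, mean = mean(values),
         std = stats::sd(values), skewness = skew, n = length(values),
         n_excluded = n_excluded, log_scale = log_scale),
    class = "df_distribution"
  )
}

#' @export
print.df_distribution <- function(x, ...) {
  cat(sprintf(
    "Pooled %s distribution: n = %d, mean = %.4f, std = %.4f, skew = %.3f\n",
    if (x$log_scale) "ln Df" else "Df", x$n, x$mean, x$std, x$skewness))
  invisible(x)
}
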