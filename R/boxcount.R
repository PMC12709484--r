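#' Count occupied boxes of a binary mask at one box size
#'
#' Partitions the mask into an axis-aligned grid of `r` x `r` cells anchored
#' at the top-left corner (ragged edge cells are included) and counts the
#' cells containing at least one foreground pixel. Grid-anchored counting
#' keeps N(r) exact on self-similar fixtures whose construction scales the
#' box sizes divide.
#'
#' @param mask Integer or logical 0/1 matrix.
#' @param r Box side in pixels (>= 1).
#' @return Integer count of occupied boxes.
#' @examples
#' count_boxes(matrix(1L, 60, 60), 6) # 100
#' @export
count_boxes <- function(mask, r) {
  stopifnot(is.matrix(mask), r >= 1)
  r <- as.integer(r)
  gi <- (seq_len(nrow(mask)) - 1L) %/% r
  gj <- (seq_len(ncol(mask)) - 1L) %/% r
  band <- rowsum(mask + 0, gi, reorder = FALSE)
  block <- rowsum(t(band), gj, reorder = FALSE)
  sum(block > 0)
}

#' Box-counting fractal dimension of a binary mask
#'
#' Fits Df as the least-squares slope of ln N(r) versus ln(1/r) over the
#' supplied box sizes, reporting the coefficient of determination of the
#' log-log fit. The default sizes `c(2, 4, 6, 10, 12)` are the scales used
#' for 60 x 60 pixel analysis regions.
#'
#' @param mask Integer or logical 0/1 matrix with at least one foreground
#'   pixel.
#' @param box_sizes At least two distinct box sides in pixels.
#' @return An object of class `boxcount_fit`: a list with `box_sizes`,
#'   `counts`, `df` (the fitted dimension) and `r2`. Has [tidy()] and
#'   [glance()] methods.
#' @examples
#' fit_dimension(make_carpet(levels = 4), box_sizes = c(3, 9, 27))$df
#' # ln 8 / ln 3 = 1.8928
#' @export
fit_dimension <- function(mask, box_sizes = c(2, 4, 6, 10, 12)) {
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (length(box_sizes) < 2L) {
    stop("need at least two distinct box sizes", call. = FALSE)
  }
  if (sum(mask) == 0) {
    stop("mask has no foreground pixels; Df is undefined", call. = FALSE)
  }
  counts <- vapply(box_sizes, function(r) count_boxes(mask, r), numeric(1))
  x <- log(1 / box_sizes)
  y <- log(counts)
  slope_fit <- ols_slope(x, y)
  structure(
    list(box_sizes = box_sizes, counts = counts,
         df = slope_fit$slope, r2 = slope_fit$r2),
    class = "boxcount_fit"
  )
}

# slope + R^2 of y ~ x; R^2 defined as 1 for an exactly constant y
ols_slope <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  slope <- sum(xc * yc) / sum(xc * xc)
  ss_tot <- sum(yc^2)
  ss_res <- sum((yc - slope * xc)^2)
  r2 <- if (ss_tot < 1e-300) 1 else 1 - ss_res / ss_tot
  list(slope = slope, intercept = mean(y) - slope * mean(x), r2 = r2)
}

#' @export
print.boxcount_fit <- function(x, ...) {
  cat(sprintf("Box-counting fit: Df = %.4f (R2 = %.4f) over %d box sizes\n",
              x$df, x$r2, length(x$box_sizes)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.boxcount_fit <- function(x, ...) {
  tibble::tibble(box_size = x$box_sizes, count = x$counts,
                 log_inv_size = log(1 / x$box_sizes),
                 log_count = log(x$counts))
}

#' @exportS3Method generics::glance
glance.boxcount_fit <- function(x, ...) {
  tibble::tibble(df = x$df, r2 = x$r2, n_sizes = length(x$box_sizes))
}

#' Per-region fractal dimension field of a grayscale image
#'
#' Binarizes the image once at `gray_level`, tiles it into
#' `region_size`-pixel regions, and fits the box-counting dimension in each.
#' Regions with no foreground have an undefined Df (ln N does not exist) and
#' are excluded from the aggregates rather than set to zero; the exclusion
#' count is recorded.
#'
#' @param img Integer grayscale matrix.
#' @param gray_level Binarization threshold (level or [threshold_spec()] row).
#' @param region_size Region side in pixels; 30, 60, 120 or 240 are the
#'   conventional scales, any value >= 2 is accepted.
#' @param box_sizes Box sides passed to [fit_dimension()].
#' @return A `df_field` tibble with one row per region: `row`, `col`,
#'   `n_foreground`, `df`, `r2` (`df` is `NA` for empty regions).
#'   Attributes: `gray_level`, `percent`, `region_size`, `box_sizes`.
#'   Use [glance()] for MeanDf / STDDf.
#' @export
df_field <- function(img, gray_level, region_size = 60,
                     box_sizes = c(2, 4, 6, 10, 12)) {
  mask <- binarize(img, gray_level)
  tiles <- tile(mask, region_size)
  out <- dplyr::mutate(
    tiles,
    n_foreground = purrr::map_int(tile, function(m) sum(m)),
    fit = purrr::map(tile, function(m) {
      if (sum(m) == 0) NULL else fit_dimension(m, box_sizes)
    }),
    df = purrr::map_dbl(fit, function(f) if (is.null(f)) NA_real_ else f$df),
    r2 = purrr::map_dbl(fit, function(f) if (is.null(f)) NA_real_ else f$r2)
  )
  out <- dplyr::select(out, row, col, n_foreground, df, r2)
  if (all(is.na(out$df))) {
    stop("every region is empty at gray level ",
         attr(mask, "gray_level"), "; no Df defined", call. = FALSE)
  }
  structure(
    out,
    gray_level = attr(mask, "gray_level"),
    percent = attr(mask, "percent"),
    region_size = as.integer(region_size),
    box_sizes = as.integer(box_sizes),
    class = c("df_field", class(out))
  )
}

#' @exportS3Method generics::glance
glance.df_field <- function(x, ...) {
  v <- x$df[!is.na(x$df)]
  tibble::tibble(
    mean_df = mean(v),
    std_df = if (length(v) > 1) stats::sd(v) else NA_real_,
    n_regions = length(v),
    n_excluded = sum(is.na(x$df)),
    gray_level = attr(x, "gray_level"),
    percent = attr(x, "percent")
  )
}
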