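#' Grayscale level to percent-of-full-scale
#'
#' The percent convention used throughout the package divides by 256 (the
#' number of representable levels), so level 110 maps to 42.96875%, level 95
#' to 37.109375% and level 80 to 31.25%. The mapping is exact rational
#' arithmetic; any rounding is display-only.
#'
#' @param gray_level Integer vector of grayscale levels in `[0, 255]`.
#' @return Numeric vector, `100 * gray_level / 256`.
#' @examples
#' percent_of(c(80, 95, 110))
#' @export
percent_of <- function(gray_level) {
  check_gray_level(gray_level)
  100 * gray_level / 256
}

#' Percent-of-full-scale back to grayscale level
#'
#' Exact inverse of [percent_of()] on the representable grid.
#'
#' @param percent Numeric vector of percentages in `[0, 100)`.
#' @return Integer grayscale levels.
#' @export
gray_of <- function(percent) {
  level <- percent * 256 / 100
  if (any(abs(level - round(level)) > 1e-9)) {
    stop("percent does not correspond to an integer grayscale level",
         call. = FALSE)
  }
  level <- as.integer(round(level))
  check_gray_level(level)
  level
}

check_gray_level <- function(gray_level) {
  if (anyNA(gray_level) || any(gray_level < 0) || any(gray_level > 255)) {
    stop("gray_level must lie in [0, 255]", call. = FALSE)
  }
  invisible(gray_level)
}

#' Build a threshold specification
#'
#' @param gray_level Integer grayscale cut level in `[0, 255]`.
#' @return A one-row tibble with `gray_level` and its `percent`
#'   representation.
#' @export
threshold_spec <- function(gray_level) {
  check_gray_level(gray_level)
  tibble::tibble(gray_level = as.integer(gray_level),
                 percent = percent_of(gray_level))
}

#' Inclusive arithmetic grid of threshold levels
#'
#' The default grid, 25 to 155 in steps of 5, spans roughly 10% to 60.5% of
#' full scale — the sweep range over which the threshold trajectories are
#' traced.
#'
#' @param start_level,stop_level Grid endpoints (inclusive), in `[0, 255]`.
#' @param step Step in grayscale levels (>= 1).
#' @return A tibble with one row per level: `gray_level`, `percent`.
#' @examples
#' threshold_grid() # 27 levels, 9.77% to 60.55%
#' @export
threshold_grid <- function(start_level = 25, stop_level = 155, step = 5) {
  check_gray_level(c(start_level, stop_level))
  if (step < 1 || stop_level < start_level) {
    stop("need start <= stop and step >= 1", call. = FALSE)
  }
  levels <- seq(as.integer(start_level), as.integer(stop_level),
                by = as.integer(step))
  threshold_spec(levels)
}

#' Binarize a grayscale image at a threshold
#'
#' Pixels at or above the threshold become foreground (1), the rest
#' background (0). Equality goes to the foreground: raising the level can
#' therefore never add foreground pixels, and level 0 makes every image
#' all-foreground.
#'
#' @param img Integer grayscale matrix, values in `[0, 255]`.
#' @param gray_level Threshold level in `[0, 255]`, or a one-row tibble from
#'   [threshold_spec()].
#' @return Integer 0/1 matrix of the same shape, with attributes
#'   `gray_level` and `percent` recording the provenance.
#' @examples
#' binarize(matrix(c(0L, 255L), 2, 2), 128)
#' @export
binarize <- function(img, gray_level) {
  validate_gray(img)
  if (is.data.frame(gray_level)) gray_level <- gray_level$gray_level
  check_gray_level(gray_level)
  stopifnot(length(gray_level) == 1L)
  mask <- matrix(as.integer(img >= gray_level), nrow(img), ncol(img))
  attr(mask, "gray_level") <- as.integer(gray_level)
  attr(mask, "percent") <- percent_of(gray_level)
  mask
}
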