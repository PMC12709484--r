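#' Read a micrograph as an 8-bit grayscale intensity matrix
#'
#' Reads a PNG or TIFF raster and returns an integer matrix of intensities on
#' the 0--255 scale, the raw substrate for all downstream analyses. 16-bit
#' inputs are rescaled linearly (255 * v / 65535, rounded); RGB inputs are
#' collapsed to luminance with the standard Rec. 601 weights
#' (0.299, 0.587, 0.114). An alpha channel, if present, is ignored.
#'
#' @param path Path to a PNG or TIFF file.
#' @return An integer matrix (rows = image rows from the top) with values in
#'   `[0, 255]`.
#' @examples
#' \donttest{
#' tmp <- tempfile(fileext = ".png")
#' write_gray(matrix(128L, 16, 16), tmp)
#' img <- read_gray(tmp)
#' range(img)
#' }
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) {
    stop("file does not exist: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (expected png/tif/tiff)",
         call. = FALSE)
  )
  as_gray_matrix(raw)
}

# Collapse a readPNG/readTIFF array ([0,1] scale) to an integer 0-255 matrix.
as_gray_matrix <- function(raw) {
  if (length(raw) == 0L) {
    stop("zero-sized image", call. = FALSE)
  }
  if (length(dim(raw)) == 3L) {
    nc <- dim(raw)[3]
    raw <- if (nc >= 3L) {
      0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3]
    } else {
      raw[, , 1]
    }
  }
  img <- matrix(as.integer(round(raw * 255)), nrow(raw), ncol(raw))
  validate_gray(img)
  img
}

validate_gray <- function(img) {
  if (!is.matrix(img) || nrow(img) < 1L || ncol(img) < 1L) {
    stop("image must be a matrix with at least one pixel", call. = FALSE)
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 255) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  invisible(img)
}

#' Write a grayscale matrix to an 8-bit PNG
#'
#' @param img Integer matrix with values in `[0, 255]` (grayscale) or `{0, 1}`
#'   (binary masks, written as black/white).
#' @param path Output path ending in `.png`.
#' @param binary If `TRUE`, treat `img` as a 0/1 mask and scale to full range.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path, binary = FALSE) {
  validate_gray(if (binary) img * 255L else img)
  scale <- if (binary) 1 else 255
  png::writePNG(img / scale, path)
  invisible(path)
}

#' Tile an image into non-overlapping square analysis regions
#'
#' Partitions the image into `region_size` x `region_size` tiles, discarding
#' any remainder rows/columns at the bottom/right edges (padding would inject
#' artificial structure into the fractal dimension). Tiles are indexed
#' 1-based, row-major: tile (1, 1) is top-left, and tile (1, 5) of a 480x480
#' image at size 60 covers pixel rows 1--60 and columns 241--300.
#'
#' @param img Grayscale or binary matrix.
#' @param region_size Tile side in pixels (>= 2).
#' @return A tibble with one row per tile: `row`, `col` (1-based tile
#'   indices) and `tile` (a list-column of matrices). The `region_size`
#'   attribute records the tile side.
#' @examples
#' tiles <- tile(matrix(0L, 480, 480), 60)
#' nrow(tiles) # 64 tiles in an 8x8 grid
#' @export
tile <- function(img, region_size) {
  stopifnot(is.matrix(img))
  region_size <- as.integer(region_size)
  if (region_size < 2L) {
    stop("region_size must be >= 2", call. = FALSE)
  }
  if (region_size > min(nrow(img), ncol(img))) {
    stop("region_size (", region_size, ") exceeds the smaller image side",
         call. = FALSE)
  }
  nr <- nrow(img) %/% region_size
  nc <- ncol(img) %/% region_size
  grid <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc))
  out <- dplyr::mutate(
    grid,
    tile = purrr::map2(row, col, function(i, j) {
      img[((i - 1L) * region_size + 1L):(i * region_size),
          ((j - 1L) * region_size + 1L):(j * region_size), drop = FALSE]
    })
  )
  attr(out, "region_size") <- region_size
  out
}

#' Reassemble tiles produced by [tile()] into one matrix
#'
#' Inverse of [tile()] up to the discarded remainder margins; used mainly to
#' verify the tiling convention.
#'
#' @param tiles A tibble from [tile()].
#' @return The cropped image matrix.
#' @export
untile <- function(tiles) {
  s <- attr(tiles, "region_size")
  nr <- max(tiles$row)
  nc <- max(tiles$col)
  out <- matrix(tiles$tile[[1]][1] * 0L, nr * s, nc * s)
  for (k in seq_len(nrow(tiles))) {
    i <- tiles$row[k]
    j <- tiles$col[k]
    out[((i - 1L) * s + 1L):(i * s), ((j - 1L) * s + 1L):(j * s)] <-
      tiles$tile[[k]]
  }
  out
}
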