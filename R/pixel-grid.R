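#' Pixel grids: the image container used throughout the package
#'
#' A pixel grid is a plain base-R numeric array of dimension
#' `c(height, width, 3)` holding RGB intensities as integers in `[0, 255]`.
#' All imaging operations consume and return this representation; conversion
#' to and from [EBImage::Image] objects (which store `x = width` first and
#' intensities in `[0, 1]`) happens only at the file I/O boundary.
#'
#' @param x An object to convert or validate.
#' @return `as_pixel_grid()` returns a `height x width x 3` numeric array with
#'   values in `[0, 255]`.
#' @examples
#' g <- as_pixel_grid(array(100, dim = c(4, 4, 3)))
#' dim(g)
#' @export
as_pixel_grid <- function(x) {
  if (inherits(x, "Image")) {
    a <- EBImage::imageData(x)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
    # EBImage is (x = col, y = row, channel); transpose to (row, col, channel)
    a <- aperm(a[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
    return(round(pmin(pmax(a * 255, 0), 255)))
  }
  x <- unclass(x)
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  validate_pixel_grid(x)
  x
}

validate_pixel_grid <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop_fdr("bad_image", "a pixel grid must be a height x width x 3 array")
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    stop_fdr("bad_image", "pixel grid dimensions must be at least 1 x 1")
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop_fdr("bad_image", "pixel values must lie in [0, 255]")
  invisible(x)
}

# to EBImage Image in [0,1], (x, y, c) order
as_ebimage <- function(grid) {
  EBImage::Image(aperm(grid, c(2L, 1L, 3L)) / 255, colormode = "Color")
}

#' Read and write fundus photographs
#'
#' Thin wrappers over [EBImage::readImage()] / [EBImage::writeImage()] that
#' convert between files (PNG or JPEG) and pixel grids. Grayscale files are
#' promoted to three identical RGB channels on read.
#'
#' @param path File path. `write_fundus()` infers the format from the
#'   extension; PNG is the recommended output format.
#' @param grid A pixel grid (see [as_pixel_grid()]).
#' @return `read_fundus()` returns a pixel grid; `write_fundus()` returns
#'   `path` invisibly.
#' @export
read_fundus <- function(path) {
  as_pixel_grid(EBImage::readImage(path))
}

#' @rdname read_fundus
#' @export
write_fundus <- function(grid, path) {
  validate_pixel_grid(grid)
  EBImage::writeImage(as_ebimage(grid), path)
  invisible(path)
}
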