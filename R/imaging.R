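#' Trim near-black borders from a fundus photograph
#'
#' Retina photographs carry a black frame around the eye. This removes every
#' contiguous border row and column in which all pixels are dark, i.e. in
#' which no pixel has any channel reaching `threshold`. Interior rows are
#' never removed: the result is the minimal bounding crop whose first and
#' last row and column each contain at least one pixel with some channel
#' `>= threshold`.
#'
#' @param grid A pixel grid (`H x W x 3` array, values 0--255).
#' @param threshold Intensity below which a pixel counts as dark, on the
#'   maximum across the three channels. Default 7: a row survives if any
#'   channel of any of its pixels is at least 7.
#' @return The cropped pixel grid. Dimensions never increase.
#' @section Errors: Signals a condition of class `fundusdr_all_dark` when
#'   every pixel of the image is dark.
#' @examples
#' g <- array(0, dim = c(6, 6, 3))
#' g[2:5, 2:5, ] <- 100
#' dim(trim_dark_borders(g))  # 4 4 3
#' @export
trim_dark_borders <- function(grid, threshold = 7) {
  validate_pixel_grid(grid)
  stopifnot(threshold >= 0, threshold <= 255)
  bright <- channel_max(grid) >= threshold
  rows <- which(apply(bright, 1L, any))
  cols <- which(apply(bright, 2L, any))
  if (length(rows) == 0L)
    stop_fdr("all_dark", sprintf(
      "every pixel has all channels below %s; nothing to keep", threshold))
  grid[min(rows):max(rows), min(cols):max(cols), , drop = FALSE]
}

channel_max <- function(grid) {
  # indexing drops dims for 1-pixel-wide grids; rebuild the matrix shape
  matrix(pmax(grid[, , 1L], grid[, , 2L], grid[, , 3L]),
         dim(grid)[1], dim(grid)[2])
}

#' Zero out everything outside the inscribed circle
#'
#' Keeps the circular eye region and blanks the rest: every pixel whose
#' center lies farther than `min(H, W) / 2` from the grid center
#' `((H - 1) / 2, (W - 1) / 2)` (zero-based pixel centers) has all channels
#' set to 0. Pixels inside the circle are untouched, so the operation is
#' idempotent and never increases any pixel value.
#'
#' @inheritParams trim_dark_borders
#' @return A pixel grid of the same dimensions.
#' @examples
#' m <- inscribe_circle_mask(array(100, dim = c(4, 4, 3)))
#' m[1, 1, 1]  # corner zeroed
#' m[2, 2, 1]  # interior kept
#' @export
inscribe_circle_mask <- function(grid) {
  validate_pixel_grid(grid)
  h <- dim(grid)[1]; w <- dim(grid)[2]
  outside <- outside_circle(h, w)
  if (any(outside)) grid[outside] <- 0
  grid
}

# logical H x W x 3 index of pixels beyond the inscribed circle
outside_circle <- function(h, w) {
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  r2 <- (min(h, w) / 2)^2
  d2 <- outer((0:(h - 1) - cy)^2, (0:(w - 1) - cx)^2, `+`)
  array(rep(d2 > r2, 3L), dim = c(h, w, 3L))
}

#' Resize an image to a square of a given side
#'
#' Forces both dimensions to `side` pixels with bilinear interpolation
#' (via [EBImage::resize()]); the aspect ratio is deliberately not
#' preserved, matching a fixed-input-size classifier.
#'
#' @inheritParams trim_dark_borders
#' @param side Target side length in pixels (default 299).
#' @return A `side x side x 3` pixel grid.
#' @export
resize_image <- function(grid, side = 299) {
  validate_pixel_grid(grid)
  stopifnot(side >= 1)
  if (dim(grid)[1] == side && dim(grid)[2] == side) return(grid)
  out <- EBImage::resize(as_ebimage(grid), w = side, h = side)
  as_pixel_grid(out)
}

#' Preprocessing configuration
#'
#' @param dark_threshold Intensity below which border pixels count as dark
#'   (default 7).
#' @param target_side Output side length in pixels (default 299).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(dark_threshold = 7, target_side = 299) {
  stopifnot(dark_threshold >= 0, dark_threshold <= 255, target_side >= 1)
  structure(list(dark_threshold = dark_threshold, target_side = target_side),
            class = "preprocess_config")
}

#' Full fundus preprocessing: trim, mask, re-trim, resize
#'
#' The standard composition applied to every photograph before training:
#' (1) trim dark borders, (2) zero everything outside the inscribed circle
#' whose diameter is the smaller of height and width, (3) trim dark borders
#' again (masking can darken whole rows near the top/bottom of a non-square
#' crop), (4) resize to `target_side` square.
#'
#' @inheritParams trim_dark_borders
#' @param config A [preprocess_config()].
#' @return A `target_side x target_side x 3` pixel grid.
#' @section Errors: Propagates `fundusdr_all_dark` for images with no pixel
#'   reaching the threshold.
#' @export
preprocess_fundus <- function(grid, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  g <- trim_dark_borders(grid, config$dark_threshold)
  g <- inscribe_circle_mask(g)
  g <- trim_dark_borders(g, config$dark_threshold)
  resize_image(g, config$target_side)
}

#' Preprocess a directory of photographs
#'
#' Applies [preprocess_fundus()] to every image listed in a manifest and
#' writes the results as PNG files, returning a manifest of what was done.
#'
#' @param manifest A data frame with column `image` (paths, relative to
#'   `in_dir` if given) as produced by [read_manifest()]; extra columns are
#'   carried through.
#' @param out_dir Output directory, created if needed.
#' @param config A [preprocess_config()].
#' @param in_dir Optional root prepended to relative manifest paths.
#' @return A tibble with columns `source_path`, `output_path`, `original_h`,
#'   `original_w` plus any label columns from the input manifest.
#' @export
preprocess_dir <- function(manifest, out_dir, config = preprocess_config(),
                           in_dir = NULL) {
  stopifnot(is.data.frame(manifest), "image" %in% names(manifest))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    src <- manifest$image[i]
    path <- if (is.null(in_dir)) src else file.path(in_dir, src)
    g <- read_fundus(path)
    out <- preprocess_fundus(g, config)
    dest <- file.path(out_dir, paste0(
      sub("\\.[^.]+$", "", basename(src)), ".png"))
    write_fundus(out, dest)
    tibble::tibble(source_path = path, output_path = dest,
                   original_h = dim(g)[1], original_w = dim(g)[2])
  })
  out <- dplyr::bind_rows(rows)
  extra <- setdiff(names(manifest), "image")
  if (length(extra)) out <- dplyr::bind_cols(out, manifest[extra])
  out
}
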