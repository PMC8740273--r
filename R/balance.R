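#' Per-class upsampling plan
#'
#' How many transformed copies to add per image so that each diseased class
#' approaches the majority (grade 0) class size. For class i with `Ni`
#' images against a majority of `N0`, the add count per image is
#' `floor((N0 - Ni) / Ni)`, giving a post-upsampling total of
#' `Ni * (add + 1) <= N0`.
#'
#' @param majority_count Number of images in the majority class (`N0`).
#' @param class_counts Integer vector of image counts for the classes to be
#'   upsampled (grades 1--4 in the usual five-grade setting).
#' @return A tibble of class `balance_plan` with columns `class` (1-based
#'   position in `class_counts`), `count`, `add_per_image`, `total`.
#' @section Errors: `fundusdr_invalid_counts` if any class count is zero or
#'   exceeds the majority count.
#' @examples
#' balance_plan(15472, c(1445, 3183, 553, 421))
#' @export
balance_plan <- function(majority_count, class_counts) {
  majority_count <- as.integer(majority_count)
  class_counts <- as.integer(class_counts)
  if (any(class_counts < 1L) || any(class_counts > majority_count))
    stop_fdr("invalid_counts",
             "class counts must be >= 1 and no larger than the majority count")
  add <- (majority_count - class_counts) %/% class_counts
  out <- tibble::tibble(
    class = seq_along(class_counts),
    count = class_counts,
    add_per_image = add,
    total = class_counts * (add + 1L)
  )
  structure(out, class = c("balance_plan", class(out)),
            majority_count = majority_count)
}

#' Mirror an image about its vertical or horizontal centerline
#'
#' `flip_lr()` reverses column order (left-right mirror); `flip_ud()`
#' reverses row order (up-down mirror). Both are involutions.
#'
#' @inheritParams trim_dark_borders
#' @return A pixel grid of the same dimensions.
#' @export
flip_lr <- function(grid) {
  validate_pixel_grid(grid)
  grid[, dim(grid)[2]:1, , drop = FALSE]
}

#' @rdname flip_lr
#' @export
flip_ud <- function(grid) {
  validate_pixel_grid(grid)
  grid[dim(grid)[1]:1, , , drop = FALSE]
}

#' Rotate an image about its center by a given or random angle
#'
#' `rotate_by()` rotates by `angle` degrees about the image center with
#' bilinear interpolation, filling exposed regions with 0 and keeping the
#' original dimensions. `rotate_random()` draws the angle uniformly from
#' [0, 360) under `seed` and is reproducible.
#'
#' @inheritParams trim_dark_borders
#' @param angle Rotation angle in degrees.
#' @param seed Integer seed for the angle draw.
#' @return A pixel grid of the same dimensions.
#' @export
rotate_by <- function(grid, angle) {
  validate_pixel_grid(grid)
  angle <- angle %% 360
  if (angle == 0) return(grid)
  out <- EBImage::rotate(as_ebimage(grid), angle,
                         output.dim = c(dim(grid)[2], dim(grid)[1]),
                         bg.col = "black")
  as_pixel_grid(out)
}

#' @rdname rotate_by
#' @export
rotate_random <- function(grid, seed) {
  rotate_by(grid, draw_angles(1L, seed))
}

draw_angles <- function(n, seed) {
  withr::with_seed(seed, stats::runif(n, 0, 360))
}

#' Delete the unnecessary area outside the circular eye region
#'
#' Rotation can push interpolation artifacts brighter than the dark
#' threshold into the corners of a square image. This re-applies the
#' inscribed circular mask (center of the image, radius half the side
#' length), zeroing everything outside. Requires a square image, the shape
#' every photograph has after preprocessing.
#'
#' @inheritParams trim_dark_borders
#' @return A pixel grid of the same dimensions with corners zeroed.
#' @section Errors: `fundusdr_not_square` when height differs from width.
#' @export
remove_unnecessary_area <- function(grid) {
  validate_pixel_grid(grid)
  if (dim(grid)[1] != dim(grid)[2])
    stop_fdr("not_square", "expected a square (post-preprocessing) image")
  inscribe_circle_mask(grid)
}

#' Upsample one class by geometric transforms
#'
#' Generates `add_per_image` additional images from every source image, in
#' the deterministic order: left-right flip first, up-down flip second, and
#' the remainder as independent random-angle rotations. Every generated
#' image is passed through [remove_unnecessary_area()] (a no-op for flips of
#' already-masked inputs). Originals are retained, so the output holds
#' `length(images) * (add_per_image + 1)` images.
#'
#' @param images A list of square pixel grids (one class).
#' @param add_per_image Non-negative integer: copies to add per source.
#' @param seed Integer seed; one independent uniform angle is drawn per
#'   generated rotation.
#' @return A list of class `augmented_set` with elements `images` (list of
#'   pixel grids) and `provenance`, a tibble with one row per output image:
#'   `source` (index into `images`), `transform` (`"source"`, `"flip_lr"`,
#'   `"flip_ud"` or `"rotate"`), `angle` (degrees, `NA` unless rotated).
#' @export
upsample_class <- function(images, add_per_image, seed = 1L) {
  stopifnot(is.list(images), add_per_image >= 0)
  add_per_image <- as.integer(add_per_image)
  n_rot <- max(add_per_image - 2L, 0L) * length(images)
  angles <- if (n_rot > 0) draw_angles(n_rot, seed) else numeric(0)
  tags <- c("flip_lr", "flip_ud", rep("rotate", max(add_per_image - 2L, 0L)))
  tags <- tags[seq_len(add_per_image)]

  out_images <- vector("list", length(images) * (add_per_image + 1L))
  prov <- vector("list", length(out_images))
  k <- 0L; rot_i <- 0L
  for (s in seq_along(images)) {
    k <- k + 1L
    out_images[[k]] <- images[[s]]
    prov[[k]] <- tibble::tibble(source = s, transform = "source",
                                angle = NA_real_)
    for (tag in tags) {
      k <- k + 1L
      ang <- NA_real_
      g <- switch(tag,
        flip_lr = flip_lr(images[[s]]),
        flip_ud = flip_ud(images[[s]]),
        rotate = {
          rot_i <- rot_i + 1L
          ang <- angles[rot_i]
          rotate_by(images[[s]], ang)
        })
      out_images[[k]] <- remove_unnecessary_area(g)
      prov[[k]] <- tibble::tibble(source = s, transform = tag, angle = ang)
    }
  }
  structure(list(images = out_images, provenance = dplyr::bind_rows(prov)),
            class = "augmented_set")
}

#' Inverse-frequency class weights
#'
#' Weight for class c is `n_samples / (n_classes * count(c))`: rarer grades
#' get proportionally larger weights, and the count-weighted mean of the
#' weights over the sample is exactly 1.
#'
#' @param labels Integer vector of grades `0 .. n_classes - 1`; every class
#'   must be present at least once.
#' @param n_classes Number of classes (default 5).
#' @return A tibble with columns `grade`, `count`, `weight`.
#' @section Errors: `fundusdr_missing_class` when any grade has no examples.
#' @examples
#' class_weights(rep(0:4, times = c(15472, 1445, 3183, 553, 421)))
#' @export
class_weights <- function(labels, n_classes = 5L) {
  labels <- as.integer(labels)
  stopifnot(all(labels >= 0L), all(labels < n_classes))
  counts <- tabulate(labels + 1L, nbins = n_classes)
  if (any(counts == 0L))
    stop_fdr("missing_class", sprintf(
      "grade(s) %s have no examples; class weights are undefined",
      paste(which(counts == 0L) - 1L, collapse = ", ")))
  tibble::tibble(
    grade = 0:(n_classes - 1L),
    count = counts,
    weight = length(labels) / (n_classes * counts)
  )
}
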