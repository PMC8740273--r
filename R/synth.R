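#' Parameters for synthetic fundus photographs
#'
#' The generator emulates the gross geometry of a retina photograph: a
#' near-black frame (all intensities strictly below 7) surrounding a bright
#' roughly-circular (elliptical, with random eccentricity) eye region,
#' optionally dotted with small bright lesion blobs.
#'
#' @param side Canvas side length in pixels.
#' @param border Width in pixels of the guaranteed-dark frame.
#' @param disc_intensity Length-2 range of the disc's base intensity.
#' @param lesions Length-2 integer range for the number of lesion blobs.
#' @param lesion_intensity Intensity of lesion blobs.
#' @return A list of class `fundus_params`.
#' @export
fundus_params <- function(side = 64L, border = 6L,
                          disc_intensity = c(100, 135),
                          lesions = c(0L, 3L), lesion_intensity = 240) {
  stopifnot(side >= 8L, border >= 0L, 2 * border < side,
            all(disc_intensity >= 7), all(disc_intensity <= 255),
            all(lesions >= 0L), lesion_intensity <= 255)
  structure(list(side = as.integer(side), border = as.integer(border),
                 disc_intensity = disc_intensity,
                 lesions = as.integer(lesions),
                 lesion_intensity = lesion_intensity),
            class = "fundus_params")
}

#' Generate one synthetic fundus photograph
#'
#' Deterministic under `seed`. The frame (everything within `border` pixels
#' of the edge, and everything outside the elliptical disc when there are
#' no lesions) stays strictly below intensity 7, so border trimming and
#' circular masking behave as on real photographs.
#'
#' @param params A [fundus_params()] object.
#' @param seed Integer seed.
#' @param grade Optional severity grade 0--4; when given, it raises the
#'   lesion count (`grade` extra blobs) and shifts the disc intensity so
#'   classes are visually distinguishable, giving desk-scale classifiers a
#'   learnable signal.
#' @return A `side x side x 3` pixel grid.
#' @export
make_fundus <- function(params = fundus_params(), seed = 1L, grade = NULL) {
  stopifnot(inherits(params, "fundus_params"))
  withr::with_seed(seed, {
    s <- params$side; b <- params$border
    # dark frame noise in [0, 6]
    g <- array(sample(0:6, s * s * 3, replace = TRUE), dim = c(s, s, 3))

    # elliptical disc inside the frame, random eccentricity
    cy <- (s + 1) / 2; cx <- (s + 1) / 2
    rmax <- (s - 2 * b) / 2
    ry <- rmax * runif(1, 0.75, 1)
    rx <- rmax * runif(1, 0.75, 1)
    base <- runif(1, params$disc_intensity[1], params$disc_intensity[2])
    if (!is.null(grade)) base <- min(base + 18 * grade, 250)
    yy <- matrix((1:s - cy) / ry, s, s)
    xx <- matrix((1:s - cx) / rx, s, s, byrow = TRUE)
    inside <- yy^2 + xx^2 <= 1
    shade <- 1 - 0.3 * (yy^2 + xx^2)     # gentle radial falloff
    tint <- c(1, 0.55, 0.35)             # fundus photographs skew red
    for (ch in 1:3) {
      plane <- g[, , ch]
      plane[inside] <- pmin(pmax(base * shade[inside] * tint[ch], 7), 255)
      g[, , ch] <- plane
    }

    # lesion blobs inside the disc
    n_les <- sample(params$lesions[1]:params$lesions[2], 1)
    if (!is.null(grade)) n_les <- n_les + grade
    for (i in seq_len(n_les)) {
      ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, 0.6)
      ly <- cy + rad * ry * sin(ang); lx <- cx + rad * rx * cos(ang)
      lr <- runif(1, 1, max(2, s / 24))
      d2 <- outer((1:s - ly)^2, (1:s - lx)^2, `+`)
      blob <- d2 <= lr^2 & inside
      for (ch in 1:3) {
        plane <- g[, , ch]
        plane[blob] <- params$lesion_intensity * tint[ch]
        g[, , ch] <- plane
      }
    }
    round(pmin(pmax(g, 0), 255))
  })
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes `sum(n_per_class)` synthetic photographs as PNG files plus a
#' manifest, with exact per-class counts and grade-dependent appearance.
#'
#' @param n_per_class Integer vector of image counts per grade, starting at
#'   grade 0 (e.g. the five-grade class-skew of a screening population,
#'   scaled down).
#' @param dir Output directory (created if needed).
#' @param params A [fundus_params()] object.
#' @param seed Integer seed; images are byte-identical across runs with the
#'   same seed.
#' @return A `labeled_dataset` tibble (columns `image`, `label`) pointing at
#'   the written files; also written as `manifest.csv` in `dir`.
#' @export
make_labelled_set <- function(n_per_class, dir,
                              params = fundus_params(), seed = 1L) {
  stopifnot(all(n_per_class >= 1L))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grades <- rep(seq_along(n_per_class) - 1L, times = n_per_class)
  paths <- character(length(grades))
  for (i in seq_along(grades)) {
    g <- make_fundus(params, seed = seed * 100000L + i, grade = grades[i])
    paths[i] <- file.path(dir, sprintf("img_%04d_g%d.png", i, grades[i]))
    write_fundus(g, paths[i])
  }
  ds <- tibble::tibble(image = paths, label = grades)
  write_manifest(ds, file.path(dir, "manifest.csv"))
  structure(ds, class = c("labeled_dataset", class(tibble::tibble())))
}

#' Skill-controlled synthetic probability matrices
#'
#' Emulates a panel of base classifiers with known accuracy: classifier i
#' predicts the true grade with probability `skills[i]` and otherwise a
#' uniformly random wrong grade; each row places `concentration` of its
#' probability mass on the chosen grade and spreads the rest uniformly.
#'
#' @param truth Integer vector of true grades `0 .. k-1`.
#' @param skills Numeric vector in `[0, 1]`, one per classifier.
#' @param concentration Probability mass on the chosen grade (default 0.8).
#' @param k Number of classes (default 5).
#' @param seed Integer seed.
#' @return A list of samples x classes probability matrices, one per
#'   classifier; rows sum to 1.
#' @export
make_prob_matrices <- function(truth, skills, concentration = 0.8,
                               k = 5L, seed = 1L) {
  truth <- as.integer(truth)
  stopifnot(all(truth >= 0L & truth < k),
            all(skills >= 0 & skills <= 1),
            concentration >= 1 / k, concentration <= 1)
  n <- length(truth)
  withr::with_seed(seed, purrr::map(skills, function(s) {
    correct <- runif(n) < s
    wrong <- (truth + sample(1:(k - 1L), n, replace = TRUE)) %% k
    chosen <- ifelse(correct, truth, wrong)
    m <- matrix((1 - concentration) / (k - 1L), n, k)
    m[cbind(seq_len(n), chosen + 1L)] <- concentration
    m
  }))
}
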