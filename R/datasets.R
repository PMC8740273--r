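#' Read or write a label manifest
#'
#' Manifests are CSV files with header `image,label` mapping an image path
#' to its severity grade 0--4 (0 = No DR, 1 = Mild, 2 = Moderate,
#' 3 = Severe, 4 = Proliferative DR). Extra columns round-trip untouched.
#'
#' @param path CSV file path.
#' @param check_files If `TRUE`, warn (`fundusdr_missing_file`) about
#'   manifest rows whose image path does not exist on disk.
#' @param n_classes Number of severity grades (default 5).
#' @return A tibble with columns `image` (character) and `label` (integer),
#'   of class `labeled_dataset`; class counts are available via
#'   [dplyr::count()] or [glance()].
#' @section Errors: `fundusdr_bad_label` for labels outside `0 .. n_classes-1`.
#' @export
read_manifest <- function(path, check_files = FALSE, n_classes = 5L) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("image", "label") %in% names(df)))
  df$label <- suppressWarnings(as.integer(df$label))
  bad <- is.na(df$label) | df$label < 0L | df$label >= n_classes
  if (any(bad))
    stop_fdr("bad_label", sprintf(
      "%d manifest label(s) outside the valid grades 0..%d",
      sum(bad), n_classes - 1L))
  if (anyDuplicated(df$image))
    stop_fdr("bad_label", "manifest image paths must be unique")
  if (check_files) {
    missing <- !file.exists(df$image)
    if (any(missing))
      rlang::warn(sprintf("%d manifest image(s) not found on disk",
                          sum(missing)),
                  class = "fundusdr_missing_file")
  }
  structure(tibble::as_tibble(df),
            class = c("labeled_dataset", class(tibble::tibble())))
}

#' @rdname read_manifest
#' @param dataset A data frame with columns `image` and `label`.
#' @export
write_manifest <- function(dataset, path) {
  stopifnot(all(c("image", "label") %in% names(dataset)))
  readr::write_csv(tibble::as_tibble(unclass(dataset)), path)
  invisible(path)
}

#' Split a labelled dataset 3:1:1 into train, validation and test sets
#'
#' The validation and test sets each receive `ceiling(N / 5)` samples and
#' the training set the remainder; with N = 35,126 this yields
#' 21,074 / 7,026 / 7,026. Assignment is a seeded uniform shuffle,
#' stratified by grade: each class contributes close to 2/5 of its images
#' to the combined holdout (largest-remainder allocation against the exact
#' global totals), so the per-class training share stays within one image
#' of 3/5.
#'
#' @param dataset A data frame with a `label` column (e.g. from
#'   [read_manifest()]).
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return The input tibble with an added factor column `set` (levels
#'   `train`, `valid`, `test`), of class `split_result`. Split sizes are in
#'   `attr(x, "sizes")` and via [glance()].
#' @export
split_311 <- function(dataset, seed = 1L) {
  stopifnot(is.data.frame(dataset), "label" %in% names(dataset),
            nrow(dataset) >= 5L)
  n <- nrow(dataset)
  n_hold <- ceiling(n / 5)           # each of valid and test
  labels <- dataset$label
  classes <- sort(unique(labels))
  n_c <- vapply(classes, function(cl) sum(labels == cl), integer(1))

  # per-class holdout h_c ~ 2 n_c / 5, largest remainder, total forced
  target <- 2 * n_c / 5
  h <- floor(target)
  need <- 2L * n_hold - sum(h)
  ord <- order(target - h, decreasing = TRUE)
  i <- 0L
  while (need > 0L) {                # at most two extra passes needed
    cl <- ord[(i %% length(ord)) + 1L]
    if (h[cl] < n_c[cl]) { h[cl] <- h[cl] + 1L; need <- need - 1L }
    i <- i + 1L
  }
  # split h_c into valid/test as evenly as possible; valid total exact
  v <- floor(h / 2)
  deficit <- n_hold - sum(v)
  odd <- which(h %% 2 == 1L)
  if (deficit > 0L) v[odd[seq_len(deficit)]] <- v[odd[seq_len(deficit)]] + 1L

  set <- character(n)
  withr::with_seed(seed, {
    for (k in seq_along(classes)) {
      idx <- sample(which(labels == classes[k]))
      set[idx[seq_len(v[k])]] <- "valid"
      set[idx[v[k] + seq_len(h[k] - v[k])]] <- "test"
      if (h[k] < length(idx))
        set[idx[(h[k] + 1L):length(idx)]] <- "train"
    }
  })
  out <- tibble::as_tibble(unclass(dataset))
  out$set <- factor(set, levels = c("train", "valid", "test"))
  sizes <- c(train = sum(set == "train"), valid = sum(set == "valid"),
             test = sum(set == "test"))
  structure(out, class = c("split_result", class(out)),
            sizes = sizes, seed = seed)
}

#' @exportS3Method generics::glance
glance.split_result <- function(x, ...) {
  s <- attr(x, "sizes")
  tibble::tibble(n = sum(s), train = s[["train"]], valid = s[["valid"]],
                 test = s[["test"]], seed = attr(x, "seed"))
}

#' Write the three split manifests
#'
#' @param split A [split_311()] result.
#' @param dir Output directory; `train.csv`, `valid.csv` and `test.csv` are
#'   written there, plus `split.json` recording the seed and sizes.
#' @return `dir`, invisibly.
#' @export
write_split <- function(split, dir) {
  stopifnot(inherits(split, "split_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in c("train", "valid", "test")) {
    part <- split[split$set == s, setdiff(names(split), "set"), drop = FALSE]
    write_manifest(part, file.path(dir, paste0(s, ".csv")))
  }
  jsonlite::write_json(
    list(seed = attr(split, "seed"), sizes = as.list(attr(split, "sizes"))),
    file.path(dir, "split.json"), auto_unbox = TRUE)
  invisible(dir)
}
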