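# Independent brute-force oracles and fixture builders shared across tests.
# Oracles are deliberately written in the most literal way possible and do
# not reuse package internals.

random_grid <- function(h, w, max_val = 255) {
  array(sample(0:max_val, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

# literal reading of border trimming: scan every row/column for any channel
# >= threshold, crop to the bounding box of the survivors
oracle_trim <- function(grid, threshold) {
  h <- dim(grid)[1]; w <- dim(grid)[2]
  row_ok <- logical(h); col_ok <- logical(w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (any(grid[i, j, ] >= threshold)) {
      row_ok[i] <- TRUE; col_ok[j] <- TRUE
    }
  }
  if (!any(row_ok)) return(NULL)
  grid[range(which(row_ok))[1]:range(which(row_ok))[2],
       range(which(col_ok))[1]:range(which(col_ok))[2], , drop = FALSE]
}

# literal per-pixel circular mask with center ((H-1)/2, (W-1)/2) and radius
# min(H, W)/2 on zero-based pixel centers
oracle_mask <- function(grid) {
  h <- dim(grid)[1]; w <- dim(grid)[2]
  cy <- (h - 1) / 2; cx <- (w - 1) / 2; r <- min(h, w) / 2
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (sqrt((i - 1 - cy)^2 + (j - 1 - cx)^2) > r) grid[i, j, ] <- 0
  }
  grid
}

# AUC by exhaustive positive-negative pair counting with half credit on ties
oracle_auc_pairs <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# a synthetic fundus-like fixture: dark frame, centered bright disc
disc_fixture <- function(side = 20, border = 4, value = 120) {
  g <- array(0, dim = c(side, side, 3))
  cy <- (side + 1) / 2; r <- (side - 2 * border) / 2
  for (i in seq_len(side)) for (j in seq_len(side))
    if ((i - cy)^2 + (j - cy)^2 <= r^2) g[i, j, ] <- value
  g
}

separable_images <- function(n_per_class = 50, k = 3, side = 32) {
  imgs <- list(); labs <- integer(0)
  for (cl in 0:(k - 1)) for (i in seq_len(n_per_class)) {
    imgs[[length(imgs) + 1L]] <- withr::with_seed(cl * 1000L + i, array(
      pmin(pmax(60 + 60 * cl + rnorm(side * side * 3, sd = 10), 0), 255),
      dim = c(side, side, 3)))
    labs <- c(labs, cl)
  }
  list(images = imgs, labels = labs)
}
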