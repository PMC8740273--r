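# Low-level layer operations for the desk-scale classifier.
#
# Everything works on a single image: feature maps are H x W x C arrays
# (column-major, channel slowest), so broadcasting a per-channel vector is
# `x * rep(v, each = H * W)` and a per-pixel map is `x * as.vector(m)`.
# Convolutions are stride-1 same-padding via im2col + matrix multiply;
# gradients are explicit.

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

# im2col index cache: maps (H, W, Cin, k) to a [H*W, k*k*Cin] matrix of
# linear indices into the zero-padded array
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(h, w, cin, k) {
  key <- paste(h, w, cin, k, sep = "x")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L
  hp <- h + 2L * p; wp <- w + 2L * p
  i0 <- rep(1:h, times = w)          # output pixel rows, column-major order
  j0 <- rep(1:w, each = h)
  m <- matrix(0L, h * w, k * k * cin)
  col <- 0L
  for (c in seq_len(cin)) for (dj in 1:k) for (di in 1:k) {
    col <- col + 1L
    m[, col] <- (c - 1L) * hp * wp + (j0 + dj - 2L) * hp + (i0 + di - 1L)
  }
  .im2col_cache[[key]] <- m
  m
}

pad_zeros <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

conv_forward <- function(x, w, b) {
  k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  h <- dim(x)[1]; wd <- dim(x)[2]
  p <- (k - 1L) %/% 2L
  idx <- im2col_index(h, wd, cin, k)
  cols <- matrix(pad_zeros(x, p)[idx], nrow(idx), ncol(idx))
  out_mat <- cols %*% matrix(w, k * k * cin, cout)
  out_mat <- out_mat + rep(b, each = h * wd)
  list(out = array(out_mat, dim = c(h, wd, cout)),
       cache = list(cols = cols, h = h, w = wd, cin = cin, k = k))
}

conv_backward <- function(dout, cache, w) {
  k <- cache$k; cin <- cache$cin; h <- cache$h; wd <- cache$w
  cout <- dim(w)[4]
  p <- (k - 1L) %/% 2L
  dout_mat <- matrix(dout, h * wd, cout)
  dw <- array(crossprod(cache$cols, dout_mat), dim = dim(w))
  db <- colSums(dout_mat)
  dcols <- dout_mat %*% t(matrix(w, k * k * cin, cout))
  idx <- im2col_index(h, wd, cin, k)
  acc <- rowsum(as.vector(dcols), group = as.vector(idx))
  dpad <- array(0, dim = c(h + 2 * p, wd + 2 * p, cin))
  dpad[as.integer(rownames(acc))] <- acc
  dx <- if (p == 0L) dpad else
    dpad[p + seq_len(h), p + seq_len(wd), , drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

avgpool2_forward <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  oi <- seq(1L, 2L * h2, by = 2L); oj <- seq(1L, 2L * w2, by = 2L)
  out <- (x[oi, oj, , drop = FALSE] + x[oi + 1L, oj, , drop = FALSE] +
          x[oi, oj + 1L, , drop = FALSE] + x[oi + 1L, oj + 1L, , drop = FALSE]) / 4
  list(out = out, cache = d)
}

avgpool2_backward <- function(dout, cache) {
  d <- cache
  h2 <- dim(dout)[1]; w2 <- dim(dout)[2]
  oi <- seq(1L, 2L * h2, by = 2L); oj <- seq(1L, 2L * w2, by = 2L)
  dx <- array(0, dim = d)
  q <- dout / 4
  dx[oi, oj, ] <- q; dx[oi + 1L, oj, ] <- q
  dx[oi, oj + 1L, ] <- q; dx[oi + 1L, oj + 1L, ] <- q
  dx
}

# ---- channel + spatial attention (CBAM-style) -------------------------------

cbam_init <- function(c_channels, reduction = 4L, seed = 1L) {
  cr <- max(1L, c_channels %/% reduction)
  withr::with_seed(seed, list(
    at_ca_w1 = matrix(rnorm(c_channels * cr, sd = sqrt(2 / c_channels)),
                      c_channels, cr),
    at_ca_b1 = numeric(cr),
    at_ca_w2 = matrix(rnorm(cr * c_channels, sd = sqrt(2 / cr)),
                      cr, c_channels),
    at_ca_b2 = numeric(c_channels),
    at_sa_w = array(rnorm(7 * 7 * 2, sd = sqrt(2 / 98)), dim = c(7, 7, 2, 1)),
    at_sa_b = 0
  ))
}

cbam_mlp <- function(v, p) {
  h <- relu(drop(v %*% p$at_ca_w1) + p$at_ca_b1)
  list(s = drop(h %*% p$at_ca_w2) + p$at_ca_b2, h = h)
}

cbam_forward <- function(x, p) {
  d <- dim(x); hw <- d[1] * d[2]; cc <- d[3]
  xm <- matrix(x, hw, cc)
  av <- colMeans(xm)
  mx_pos <- max.col(t(xm), ties.method = "first")   # spatial argmax per channel
  mx <- xm[cbind(mx_pos, seq_len(cc))]
  ba <- cbam_mlp(av, p); bm <- cbam_mlp(mx, p)
  gc <- sigmoid(ba$s + bm$s)
  x1 <- x * rep(gc, each = hw)

  x1m <- matrix(x1, hw, cc)
  u <- rowSums(x1m) / cc
  amx <- max.col(x1m, ties.method = "first")        # channel argmax per pixel
  v <- x1m[cbind(seq_len(hw), amx)]
  st <- array(c(u, v), dim = c(d[1], d[2], 2L))
  cv <- conv_forward(st, p$at_sa_w, p$at_sa_b)
  gs <- sigmoid(as.vector(cv$out))
  out <- x1 * gs                                    # recycles per channel
  list(out = out,
       cache = list(x = x, x1 = x1, gc = gc, gs = gs, av = av, mx = mx,
                    mx_pos = mx_pos, amx = amx, ba = ba, bm = bm, cv = cv,
                    d = d))
}

cbam_backward <- function(dout, cache, p) {
  d <- cache$d; hw <- d[1] * d[2]; cc <- d[3]
  x1m <- matrix(cache$x1, hw, cc)
  dom <- matrix(dout, hw, cc)

  # spatial gate
  dgs <- rowSums(x1m * dom)
  dx1 <- dout * cache$gs
  dz <- dgs * cache$gs * (1 - cache$gs)
  cb <- conv_backward(array(dz, dim = c(d[1], d[2], 1L)), cache$cv$cache,
                      p$at_sa_w)
  du <- as.vector(cb$dx[, , 1L]); dv <- as.vector(cb$dx[, , 2L])
  dx1 <- dx1 + rep(du / cc, times = cc)
  dxm_route <- matrix(0, hw, cc)
  dxm_route[cbind(seq_len(hw), cache$amx)] <- dv
  dx1 <- dx1 + array(dxm_route, dim = d)

  # channel gate
  dx1m <- matrix(dx1, hw, cc)
  xm <- matrix(cache$x, hw, cc)
  dgc <- colSums(xm * dx1m)
  dx <- dx1 * rep(cache$gc, each = hw)
  ds <- dgc * cache$gc * (1 - cache$gc)

  mlp_back <- function(v, branch) {
    dh <- drop(ds %*% t(p$at_ca_w2)) * (branch$h > 0)
    list(dw1 = outer(v, dh), db1 = dh,
         dw2 = outer(branch$h, ds), db2 = ds,
         dv = drop(dh %*% t(p$at_ca_w1)))
  }
  ga <- mlp_back(cache$av, cache$ba)
  gm <- mlp_back(cache$mx, cache$bm)

  dx <- dx + rep(ga$dv / hw, each = hw)             # mean-pool branch
  dxm2 <- matrix(dx, hw, cc)                        # max-pool branch routing
  route <- cbind(cache$mx_pos, seq_len(cc))
  dxm2[route] <- dxm2[route] + gm$dv
  dx <- array(dxm2, dim = d)

  grads <- list(at_ca_w1 = ga$dw1 + gm$dw1, at_ca_b1 = ga$db1 + gm$db1,
                at_ca_w2 = ga$dw2 + gm$dw2, at_ca_b2 = ga$db2 + gm$db2,
                at_sa_w = cb$dw, at_sa_b = cb$db)
  list(dx = dx, grads = grads)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, subset = names(params)) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in intersect(subset, names(grads))) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}
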