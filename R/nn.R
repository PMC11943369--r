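# Minimal CPU neural-network kernels.
#
# Feature maps are dense arrays (H, W, C); the matrix view (H*W, C) is free
# because the spatial dims are contiguous. Convolutions are im2col + BLAS
# matrix products; every layer returns its forward cache so the paired
# *_b() function can compute exact gradients. All convolutions use zero
# padding, so spatial dimensions are preserved end to end.

mat_view <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

# He-initialized 3x3 conv parameters; weight matrix is (9*cin) x cout with
# rows ordered channel-fastest within each kernel tap
conv3_init <- function(cin, cout) {
  list(W = matrix(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                  9 * cin, cout),
       b = numeric(cout))
}

im2col_gather <- function(xm, h, w, cin) {
  im2col3_cpp(xm, h, w, cin)
}

# reorder W ((9*cin) x cout) into the flipped-kernel form ((9*cout) x cin)
# so that the input gradient is itself a convolution of dy
flip_weights <- function(W, cin, cout) {
  a <- array(W, c(cin, 9L, cout))
  a <- a[, 9:1, , drop = FALSE]
  wf <- aperm(a, c(3L, 2L, 1L))
  dim(wf) <- c(9L * cout, cin)
  wf
}

conv3_f <- function(x, p) {
  d <- dim(x)
  cols <- im2col_gather(mat_view(x), d[1], d[2], d[3])
  y <- cols %*% p$W
  y <- y + rep(p$b, each = nrow(y))
  dim(y) <- c(d[1], d[2], ncol(p$W))
  list(y = y, cache = list(cols = cols, dims = d))
}

conv3_b <- function(dy, cache, p) {
  d <- cache$dims
  ddy <- dim(dy)
  dym <- mat_view(dy)
  dW <- crossprod(cache$cols, dym)
  db <- colSums(dym)
  cout <- ncol(dym)
  dycols <- im2col_gather(dym, ddy[1], ddy[2], cout)
  dx <- dycols %*% flip_weights(p$W, d[3], cout)
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

conv1_init <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

conv1_f <- function(x, p) {
  d <- dim(x)
  y <- mat_view(x) %*% p$W
  y <- y + rep(p$b, each = nrow(y))
  dim(y) <- c(d[1], d[2], ncol(p$W))
  list(y = y, cache = list(xm = mat_view(x), dims = d))
}

conv1_b <- function(dy, cache, p) {
  dym <- mat_view(dy)
  dx <- dym %*% t(p$W)
  dim(dx) <- cache$dims
  list(dx = dx, dW = crossprod(cache$xm, dym), db = colSums(dym))
}

# PReLU with one learnable slope per channel (init 0.25)
prelu_init <- function(c) list(a = rep(0.25, c))

prelu_f <- function(x, p) {
  d <- dim(x)
  xm <- mat_view(x)
  am <- rep(p$a, each = nrow(xm))
  y <- pmax(xm, 0) + am * pmin(xm, 0)
  dim(y) <- d
  list(y = y, cache = list(xm = xm, dims = d))
}

prelu_b <- function(dy, cache, p) {
  dym <- mat_view(dy)
  am <- rep(p$a, each = nrow(dym))
  dx <- dym * ((cache$xm > 0) + am * (cache$xm <= 0))
  dim(dx) <- cache$dims
  list(dx = dx, da = colSums(dym * pmin(cache$xm, 0)))
}

relu_f <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_b <- function(dy, cache) dy * cache

# 2x2 max pooling, stride 2; ties resolved in fixed window order
maxpool2_f <- function(x) {
  d <- dim(x)
  oi <- seq(1L, d[1], 2L); ei <- oi + 1L
  oj <- seq(1L, d[2], 2L); ej <- oj + 1L
  a <- x[oi, oj, , drop = FALSE]; b <- x[ei, oj, , drop = FALSE]
  cc <- x[oi, ej, , drop = FALSE]; dd <- x[ei, ej, , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  wa <- a == y
  wb <- (b == y) & !wa
  wc <- (cc == y) & !wa & !wb
  wd <- !wa & !wb & !wc
  list(y = y, cache = list(wa = wa, wb = wb, wc = wc, wd = wd, dims = d))
}

maxpool2_b <- function(dy, cache) {
  d <- cache$dims
  oi <- seq(1L, d[1], 2L); ei <- oi + 1L
  oj <- seq(1L, d[2], 2L); ej <- oj + 1L
  dx <- array(0, d)
  half <- dim(dy)
  put <- function(mask) { t <- array(0, half); t[mask] <- dy[mask]; t }
  dx[oi, oj, ] <- put(cache$wa)
  dx[ei, oj, ] <- put(cache$wb)
  dx[oi, ej, ] <- put(cache$wc)
  dx[ei, ej, ] <- put(cache$wd)
  dx
}

# 2x2 transposed convolution, stride 2 (learned upsampling)
upconv2_init <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cin * 4 * cout, 0, sqrt(2 / cin)), cin, 4 * cout),
       b = numeric(cout))
}

upconv2_f <- function(x, p) {
  d <- dim(x)
  cout <- length(p$b)
  m <- mat_view(x) %*% p$W
  y <- array(0, c(2L * d[1], 2L * d[2], cout))
  oi <- seq(1L, 2L * d[1], 2L); ei <- oi + 1L
  oj <- seq(1L, 2L * d[2], 2L); ej <- oj + 1L
  q <- function(k) array(m[, (k - 1L) * cout + seq_len(cout)], c(d[1], d[2], cout))
  y[oi, oj, ] <- q(1L); y[ei, oj, ] <- q(2L)
  y[oi, ej, ] <- q(3L); y[ei, ej, ] <- q(4L)
  y <- y + rep(p$b, each = 4L * d[1] * d[2])
  list(y = y, cache = list(xm = mat_view(x), dims = d))
}

upconv2_b <- function(dy, cache, p) {
  d <- cache$dims
  cout <- length(p$b)
  oi <- seq(1L, 2L * d[1], 2L); ei <- oi + 1L
  oj <- seq(1L, 2L * d[2], 2L); ej <- oj + 1L
  dm <- matrix(0, d[1] * d[2], 4L * cout)
  grab <- function(a) { dim(a) <- c(d[1] * d[2], cout); a }
  dm[, 0L * cout + seq_len(cout)] <- grab(dy[oi, oj, , drop = FALSE])
  dm[, 1L * cout + seq_len(cout)] <- grab(dy[ei, oj, , drop = FALSE])
  dm[, 2L * cout + seq_len(cout)] <- grab(dy[oi, ej, , drop = FALSE])
  dm[, 3L * cout + seq_len(cout)] <- grab(dy[ei, ej, , drop = FALSE])
  dx <- dm %*% t(p$W)
  dim(dx) <- d
  list(dx = dx, dW = crossprod(cache$xm, dm), db = colSums(mat_view(dy)))
}

# squeeze-and-excitation channel attention: global average pool ->
# bottleneck (reduction r) -> sigmoid gate per channel
se_init <- function(c, reduction = 4L) {
  hid <- max(1L, c %/% reduction)
  list(W1 = matrix(stats::rnorm(hid * c, 0, sqrt(2 / c)), hid, c),
       b1 = numeric(hid),
       W2 = matrix(stats::rnorm(c * hid, 0, sqrt(2 / hid)), c, hid),
       b2 = numeric(c))
}

se_f <- function(x, p) {
  d <- dim(x)
  xm <- mat_view(x)
  s <- colMeans(xm)
  z1 <- drop(p$W1 %*% s) + p$b1
  h1 <- pmax(z1, 0)
  z2 <- drop(p$W2 %*% h1) + p$b2
  wch <- 1 / (1 + exp(-z2))
  y <- xm * rep(wch, each = nrow(xm))
  dim(y) <- d
  list(y = y, weights = wch,
       cache = list(xm = xm, s = s, z1 = z1, h1 = h1, wch = wch, dims = d))
}

se_b <- function(dy, cache, p) {
  d <- cache$dims
  n <- d[1] * d[2]
  dym <- mat_view(dy)
  dwch <- colSums(dym * cache$xm)
  dxm <- dym * rep(cache$wch, each = n)
  dz2 <- dwch * cache$wch * (1 - cache$wch)
  dW2 <- outer(dz2, cache$h1)
  dh1 <- drop(crossprod(p$W2, dz2))
  dz1 <- dh1 * (cache$z1 > 0)
  dW1 <- outer(dz1, cache$s)
  ds <- drop(crossprod(p$W1, dz1))
  dxm <- dxm + rep(ds / n, each = n)
  dim(dxm) <- d
  list(dx = dxm, dW1 = dW1, db1 = dz1, dW2 = dW2, db2 = dz2)
}

# hard clamp to [0,1]; gradient passes only where the input is interior
clamp01_f <- function(x) list(y = pmin(pmax(x, 0), 1), cache = x > 0 & x < 1)
clamp01_b <- function(dy, cache) dy * cache

softmax3 <- function(logits) {
  d <- dim(logits)
  m <- mat_view(logits)
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  m <- m - mx
  e <- exp(m)
  p <- e / rowSums(e)
  dim(p) <- d
  p
}

# ---- flat parameter lists + Adam ------------------------------------------

# Parameters live in flat named lists of numeric arrays; gradients mirror
# the names. `accumulate_grads` sums streams from several samples.
zero_like <- function(params) lapply(params, function(p) p * 0)

accumulate_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)

adam_init <- function(params)
  list(m = zero_like(params), v = zero_like(params), t = 0L)

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
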