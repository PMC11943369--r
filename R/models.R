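#' Network configurations
#'
#' `fusion_config()` describes the dual-branch fusion network: each branch is
#' three 3x3 convolutions with PReLU activations; the two branch outputs are
#' concatenated, gated by squeeze-and-excitation channel attention, and
#' reconstructed by three further 3x3 convolutions into an 8-band fused
#' image. The three-layer structure and 3x3 kernels are fixed; channel width
#' and attention reduction are tunable.
#'
#' @param branch_channels feature maps per branch convolution.
#' @param attention_reduction bottleneck reduction of the attention gate.
#' @return A `fusion_config` / `unet_config` list.
#' @export
fusion_config <- function(branch_channels = 32L, attention_reduction = 4L) {
  stopifnot(branch_channels >= 1L, attention_reduction >= 1L)
  structure(list(branch_channels = as.integer(branch_channels),
                 n_branch_layers = 3L, kernel = 3L, recon_layers = 3L,
                 attention_reduction = as.integer(attention_reduction),
                 out_bands = 8L),
            class = "fusion_config")
}

#' @rdname fusion_config
#' @param in_channels input channels of the segmentation network.
#' @param n_classes number of output classes (>= 2).
#' @param depth number of pooling stages; inputs must be divisible by
#'   `2^depth`.
#' @param base_filters channels of the first encoder level (doubled per
#'   level).
#' @param activation `"prelu"` (default) or `"relu"` for the convolution
#'   blocks; parametric units keep gradients alive in narrow networks.
#' @export
unet_config <- function(in_channels = 8L, n_classes = 3L, depth = 4L,
                        base_filters = 32L,
                        activation = c("prelu", "relu")) {
  stopifnot(n_classes >= 2L, depth >= 1L, base_filters >= 1L)
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 activation = match.arg(activation),
                 padding = "zero"),
            class = "unet_config")
}

# ---- PIF-Net ---------------------------------------------------------------

pifnet_init <- function(cfg) {
  f <- cfg$branch_channels
  p <- list()
  for (br in c("vis", "nir")) {
    cin <- 8L
    for (l in 1:3) {
      cv <- conv3_init(cin, f)
      p[[paste0(br, l, ".W")]] <- cv$W
      p[[paste0(br, l, ".b")]] <- cv$b
      p[[paste0(br, l, ".a")]] <- prelu_init(f)$a
      cin <- f
    }
  }
  se <- se_init(2L * f, cfg$attention_reduction)
  p[["att.W1"]] <- se$W1; p[["att.b1"]] <- se$b1
  p[["att.W2"]] <- se$W2; p[["att.b2"]] <- se$b2
  rc <- c(2L * f, f, f)
  ro <- c(f, f, cfg$out_bands)
  for (l in 1:3) {
    cv <- conv3_init(rc[l], ro[l])
    if (l == 3) {
      # the output layer adds onto the band-wise VIS/NIR mean (residual
      # reconstruction); start it small so the initial fused image is the
      # mean cube itself, inside the [0,1] clamp with gradients flowing
      cv$W <- cv$W * 0.1
    }
    p[[paste0("rec", l, ".W")]] <- cv$W
    p[[paste0("rec", l, ".b")]] <- cv$b
    if (l < 3) p[[paste0("rec", l, ".a")]] <- prelu_init(ro[l])$a
  }
  p
}

pif_branch_f <- function(x, p, br) {
  caches <- vector("list", 6L)
  for (l in 1:3) {
    cv <- conv3_f(x, list(W = p[[paste0(br, l, ".W")]],
                          b = p[[paste0(br, l, ".b")]]))
    ac <- prelu_f(cv$y, list(a = p[[paste0(br, l, ".a")]]))
    caches[[2L * l - 1L]] <- cv$cache
    caches[[2L * l]] <- ac$cache
    x <- ac$y
  }
  list(y = x, caches = caches)
}

pif_branch_b <- function(dy, caches, p, br) {
  g <- list()
  for (l in 3:1) {
    ab <- prelu_b(dy, caches[[2L * l]], list(a = p[[paste0(br, l, ".a")]]))
    g[[paste0(br, l, ".a")]] <- ab$da
    cb <- conv3_b(ab$dx, caches[[2L * l - 1L]],
                  list(W = p[[paste0(br, l, ".W")]]))
    g[[paste0(br, l, ".W")]] <- cb$dW
    g[[paste0(br, l, ".b")]] <- cb$db
    dy <- cb$dx
  }
  list(dx = dy, grads = g)
}

# The reconstruction is residual: the three conv layers predict a
# correction added to the band-wise mean of the VIS and NIR cubes before
# clamping. The fused image therefore starts as the mean cube and the
# network learns how to reweight it, which conditions joint training well.
pifnet_forward <- function(visx, nirx, p) {
  bv <- pif_branch_f(visx, p, "vis")
  bn <- pif_branch_f(nirx, p, "nir")
  d <- dim(bv$y)
  fcat <- array(c(bv$y, bn$y), c(d[1], d[2], 2L * d[3]))
  att <- se_f(fcat, list(W1 = p[["att.W1"]], b1 = p[["att.b1"]],
                         W2 = p[["att.W2"]], b2 = p[["att.b2"]]))
  x <- att$y
  rcaches <- list()
  for (l in 1:3) {
    cv <- conv3_f(x, list(W = p[[paste0("rec", l, ".W")]],
                          b = p[[paste0("rec", l, ".b")]]))
    rcaches[[paste0("c", l)]] <- cv$cache
    x <- cv$y
    if (l < 3) {
      ac <- prelu_f(x, list(a = p[[paste0("rec", l, ".a")]]))
      rcaches[[paste0("a", l)]] <- ac$cache
      x <- ac$y
    }
  }
  cl <- clamp01_f(x + 0.5 * (visx + nirx))
  list(fused = cl$y, attention = att$weights,
       cache = list(bv = bv$caches, bn = bn$caches, att = att$cache,
                    rec = rcaches, clamp = cl$cache, fdim = d))
}

pifnet_backward <- function(dfused, cache, p) {
  g <- list()
  dy <- clamp01_b(dfused, cache$clamp)
  for (l in 3:1) {
    if (l < 3) {
      ab <- prelu_b(dy, cache$rec[[paste0("a", l)]],
                    list(a = p[[paste0("rec", l, ".a")]]))
      g[[paste0("rec", l, ".a")]] <- ab$da
      dy <- ab$dx
    }
    cb <- conv3_b(dy, cache$rec[[paste0("c", l)]],
                  list(W = p[[paste0("rec", l, ".W")]]))
    g[[paste0("rec", l, ".W")]] <- cb$dW
    g[[paste0("rec", l, ".b")]] <- cb$db
    dy <- cb$dx
  }
  sb <- se_b(dy, cache$att, list(W1 = p[["att.W1"]], W2 = p[["att.W2"]]))
  g[["att.W1"]] <- sb$dW1; g[["att.b1"]] <- sb$db1
  g[["att.W2"]] <- sb$dW2; g[["att.b2"]] <- sb$db2
  f <- cache$fdim[3]
  dvisf <- sb$dx[, , seq_len(f), drop = FALSE]
  dnirf <- sb$dx[, , f + seq_len(f), drop = FALSE]
  bvb <- pif_branch_b(dvisf, cache$bv, p, "vis")
  bnb <- pif_branch_b(dnirf, cache$bn, p, "nir")
  list(grads = c(g, bvb$grads, bnb$grads), dvis = bvb$dx, dnir = bnb$dx)
}

# ---- U-Net -----------------------------------------------------------------

unet_channels <- function(cfg) cfg$base_filters * 2L^(seq_len(cfg$depth) - 1L)

unet_init <- function(cfg) {
  ch <- unet_channels(cfg)
  p <- list()
  add_block <- function(p, nm, cin, cout) {
    cv <- conv3_init(cin, cout)
    p[[paste0(nm, ".W")]] <- cv$W
    p[[paste0(nm, ".b")]] <- cv$b
    if (cfg$activation == "prelu")
      p[[paste0(nm, ".a")]] <- prelu_init(cout)$a
    p
  }
  cin <- cfg$in_channels
  for (l in seq_len(cfg$depth)) {
    p <- add_block(p, paste0("enc", l, ".c1"), cin, ch[l])
    p <- add_block(p, paste0("enc", l, ".c2"), ch[l], ch[l])
    cin <- ch[l]
  }
  cb <- cfg$base_filters * 2L^cfg$depth
  p <- add_block(p, "bott.c1", cin, cb)
  p <- add_block(p, "bott.c2", cb, cb)
  prev <- cb
  for (l in rev(seq_len(cfg$depth))) {
    up <- upconv2_init(prev, ch[l])
    p[[paste0("dec", l, ".up.W")]] <- up$W; p[[paste0("dec", l, ".up.b")]] <- up$b
    p <- add_block(p, paste0("dec", l, ".c1"), 2L * ch[l], ch[l])
    p <- add_block(p, paste0("dec", l, ".c2"), ch[l], ch[l])
    prev <- ch[l]
  }
  hd <- conv1_init(ch[1], cfg$n_classes)
  p[["head.W"]] <- hd$W; p[["head.b"]] <- hd$b
  p
}

conv_act_f <- function(x, p, nm, cache, act) {
  cv <- conv3_f(x, list(W = p[[paste0(nm, ".W")]], b = p[[paste0(nm, ".b")]]))
  if (act == "prelu") {
    ac <- prelu_f(cv$y, list(a = p[[paste0(nm, ".a")]]))
    cache[[nm]] <- list(conv = cv$cache, act = ac$cache)
    list(y = ac$y, cache = cache)
  } else {
    rl <- relu_f(cv$y)
    cache[[nm]] <- list(conv = cv$cache, act = rl$cache)
    list(y = rl$y, cache = cache)
  }
}

conv_act_b <- function(dy, p, nm, cache, g, act) {
  if (act == "prelu") {
    ab <- prelu_b(dy, cache[[nm]]$act, list(a = p[[paste0(nm, ".a")]]))
    g[[paste0(nm, ".a")]] <- ab$da
    dy <- ab$dx
  } else {
    dy <- relu_b(dy, cache[[nm]]$act)
  }
  cb <- conv3_b(dy, cache[[nm]]$conv, list(W = p[[paste0(nm, ".W")]]))
  g[[paste0(nm, ".W")]] <- cb$dW
  g[[paste0(nm, ".b")]] <- cb$db
  list(dx = cb$dx, grads = g)
}

unet_forward <- function(x, p, cfg) {
  d <- dim(x)
  if (d[3] != cfg$in_channels)
    stop(sprintf("expected %d input channels, got %d", cfg$in_channels, d[3]))
  if (d[1] %% 2L^cfg$depth || d[2] %% 2L^cfg$depth)
    stop(sprintf("input size must be divisible by 2^depth = %d", 2L^cfg$depth))
  cache <- list()
  skips <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    r <- conv_act_f(x, p, paste0("enc", l, ".c1"), cache, cfg$activation); cache <- r$cache
    r <- conv_act_f(r$y, p, paste0("enc", l, ".c2"), cache, cfg$activation); cache <- r$cache
    skips[[l]] <- r$y
    mp <- maxpool2_f(r$y)
    cache[[paste0("pool", l)]] <- mp$cache
    x <- mp$y
  }
  r <- conv_act_f(x, p, "bott.c1", cache, cfg$activation); cache <- r$cache
  r <- conv_act_f(r$y, p, "bott.c2", cache, cfg$activation); cache <- r$cache
  x <- r$y
  for (l in rev(seq_len(cfg$depth))) {
    up <- upconv2_f(x, list(W = p[[paste0("dec", l, ".up.W")]],
                            b = p[[paste0("dec", l, ".up.b")]]))
    cache[[paste0("up", l)]] <- up$cache
    du <- dim(up$y)
    x <- array(c(skips[[l]], up$y), c(du[1], du[2], 2L * du[3]))
    cache[[paste0("cat", l)]] <- du[3]
    r <- conv_act_f(x, p, paste0("dec", l, ".c1"), cache, cfg$activation); cache <- r$cache
    r <- conv_act_f(r$y, p, paste0("dec", l, ".c2"), cache, cfg$activation); cache <- r$cache
    x <- r$y
  }
  hd <- conv1_f(x, list(W = p[["head.W"]], b = p[["head.b"]]))
  cache[["head"]] <- hd$cache
  list(logits = hd$y, cache = cache)
}

unet_backward <- function(dlogits, cache, p, cfg) {
  g <- list()
  hb <- conv1_b(dlogits, cache[["head"]], list(W = p[["head.W"]]))
  g[["head.W"]] <- hb$dW; g[["head.b"]] <- hb$db
  dy <- hb$dx
  dskips <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    r <- conv_act_b(dy, p, paste0("dec", l, ".c2"), cache, g, cfg$activation); g <- r$grads
    r <- conv_act_b(r$dx, p, paste0("dec", l, ".c1"), cache, g, cfg$activation); g <- r$grads
    cs <- cache[[paste0("cat", l)]]
    dskips[[l]] <- r$dx[, , seq_len(cs), drop = FALSE]
    dup <- r$dx[, , cs + seq_len(cs), drop = FALSE]
    ub <- upconv2_b(dup, cache[[paste0("up", l)]],
                    list(W = p[[paste0("dec", l, ".up.W")]],
                         b = p[[paste0("dec", l, ".up.b")]]))
    g[[paste0("dec", l, ".up.W")]] <- ub$dW
    g[[paste0("dec", l, ".up.b")]] <- ub$db
    dy <- ub$dx
  }
  r <- conv_act_b(dy, p, "bott.c2", cache, g, cfg$activation); g <- r$grads
  r <- conv_act_b(r$dx, p, "bott.c1", cache, g, cfg$activation); g <- r$grads
  dy <- r$dx
  for (l in rev(seq_len(cfg$depth))) {
    dy <- maxpool2_b(dy, cache[[paste0("pool", l)]])
    dy <- dy + dskips[[l]]
    r <- conv_act_b(dy, p, paste0("enc", l, ".c2"), cache, g, cfg$activation); g <- r$grads
    r <- conv_act_b(r$dx, p, paste0("enc", l, ".c1"), cache, g, cfg$activation); g <- r$grads
    dy <- r$dx
  }
  list(grads = g, dx = dy)
}

# ---- loss ------------------------------------------------------------------

onehot <- function(labels, n_classes) {
  y <- matrix(0, length(labels), n_classes)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}

# combined soft-Dice (foreground classes) + cross-entropy, with gradient
# with respect to the logits
loss_and_grad <- function(logits, labels, n_classes, w_dice = 1, w_ce = 1) {
  d <- dim(logits)
  n <- d[1] * d[2]
  probs <- softmax3(logits)
  pm <- mat_view(probs)
  lv <- as.vector(labels)
  if (max(lv) >= n_classes) stop("class id exceeds n_classes")
  y <- onehot(lv, n_classes)
  ce <- -mean(log(pm[cbind(seq_len(n), lv + 1L)] + 1e-12))
  dce <- (pm - y) / n
  fg <- seq.int(2L, n_classes)
  dp <- matrix(0, n, n_classes)
  dvals <- numeric(length(fg))
  for (i in seq_along(fg)) {
    cc <- fg[i]
    gcol <- y[, cc]; pcol <- pm[, cc]
    den <- sum(pcol) + sum(gcol)
    if (den == 0) { dvals[i] <- 1; next }
    num <- 2 * sum(pcol * gcol)
    dvals[i] <- num / den
    dp[, cc] <- -(2 * gcol * den - num) / (den^2) / length(fg)
  }
  ldice <- 1 - mean(dvals)
  rowdot <- rowSums(dp * pm)
  ddice <- pm * (dp - rowdot)
  dlogits <- w_ce * dce + w_dice * ddice
  dim(dlogits) <- d
  pred <- max.col(pm, ties.method = "first") - 1L
  list(loss = w_ce * ce + w_dice * ldice,
       dice_loss = ldice, ce = ce,
       accuracy = mean(pred == lv),
       dlogits = dlogits, probs = probs)
}

#' Segmentation training loss
#'
#' `w_dice * (1 - soft Dice averaged over foreground classes) + w_ce *
#' cross-entropy`. The soft Dice of a class is
#' `2 * sum(p * g) / (sum(p) + sum(g))` computed on the predicted
#' probabilities; it reaches 1 (zero loss contribution) exactly for one-hot
#' correct predictions.
#'
#' @param probs H x W x C class-probability array (rows summing to 1).
#' @param truth a [label_mask] or integer matrix of true class ids.
#' @param weights length-2 vector `(w_dice, w_ce)`.
#' @return Scalar loss (>= 0).
#' @export
segmentation_loss <- function(probs, truth, weights = c(1, 1)) {
  g <- if (inherits(truth, "label_mask")) truth$labels else truth
  d <- dim(probs)
  if (!identical(dim(g), d[1:2])) stop("shape mismatch")
  n_classes <- d[3]
  if (max(g) >= n_classes) stop("class id exceeds the number of classes")
  pm <- mat_view(probs)
  lv <- as.vector(g)
  y <- onehot(lv, n_classes)
  ce <- -mean(log(pm[cbind(seq_along(lv), lv + 1L)] + 1e-12))
  fg <- seq.int(2L, n_classes)
  dvals <- vapply(fg, function(cc) {
    den <- sum(pm[, cc]) + sum(y[, cc])
    if (den == 0) 1 else 2 * sum(pm[, cc] * y[, cc]) / den
  }, 1)
  weights[1] * (1 - mean(dvals)) + weights[2] * ce
}

# ---- user-facing network operations ---------------------------------------

#' Run one feature-extraction branch of the fusion network
#'
#' @param cube an 8-band [multispectral_image] matching `branch`.
#' @param branch `"VIS"` or `"NIR"`; the two branches share structure but
#'   have independent weights.
#' @param model a fitted or freshly initialized [weedseg] model with a
#'   fusion stage.
#' @return H x W x F feature array.
#' @export
extract_branch_features <- function(cube, branch = c("VIS", "NIR"), model) {
  branch <- match.arg(branch)
  stopifnot(inherits(cube, "multispectral_image"))
  if (cube$domain_tag != branch)
    stop("cube domain does not match the requested branch")
  if (is.null(model$pif)) stop("model has no fusion stage")
  pif_branch_f(cube$pixels, model$pif, tolower(branch))$y
}

#' Fuse VIS and NIR feature maps with channel attention
#'
#' Concatenates the two maps, derives a per-channel gate in (0, 1) by global
#' average pooling through a bottleneck, and rescales each channel.
#'
#' @param f_vis,f_nir H x W x F feature arrays of equal size.
#' @param model a model with a fusion stage.
#' @return H x W x 2F gated feature array; attention weights in attribute
#'   `"attention"`.
#' @export
fuse_features <- function(f_vis, f_nir, model) {
  if (!identical(dim(f_vis)[1:2], dim(f_nir)[1:2]))
    stop("spatial size mismatch between branches")
  d <- dim(f_vis)
  fcat <- array(c(f_vis, f_nir), c(d[1], d[2], dim(f_vis)[3] + dim(f_nir)[3]))
  p <- model$pif
  att <- se_f(fcat, list(W1 = p[["att.W1"]], b1 = p[["att.b1"]],
                         W2 = p[["att.W2"]], b2 = p[["att.b2"]]))
  structure(att$y, attention = att$weights)
}

#' Reconstruct the fused 8-band image from gated features
#'
#' Three 3x3 convolution layers map the gated features to an 8-band
#' correction; when the source cubes are supplied the correction is added
#' to their band-wise mean (residual reconstruction, as used by the full
#' pipeline) before clamping to `[0, 1]`.
#'
#' @param fused H x W x 2F array from [fuse_features()].
#' @param model a model with a fusion stage.
#' @param vis,nir optional source cubes for the residual term.
#' @return An 8-band `"FUSED"` [multispectral_image], values in `[0, 1]`.
#' @export
reconstruct_fused <- function(fused, model, vis = NULL, nir = NULL) {
  p <- model$pif
  x <- fused
  for (l in 1:3) {
    x <- conv3_f(x, list(W = p[[paste0("rec", l, ".W")]],
                         b = p[[paste0("rec", l, ".b")]]))$y
    if (l < 3) x <- prelu_f(x, list(a = p[[paste0("rec", l, ".a")]]))$y
  }
  if (!is.null(vis) && !is.null(nir)) {
    vpx <- if (inherits(vis, "multispectral_image")) vis$pixels else vis
    npx <- if (inherits(nir, "multispectral_image")) nir$pixels else nir
    x <- x + 0.5 * (vpx + npx)
  }
  multispectral_image(clamp01(x), default_band_centers("FUSED"), "FUSED")
}

#' Forward pass of the zero-padded segmentation network
#'
#' @param image a [multispectral_image] (or raw array) whose channel count
#'   matches the model and whose height/width divide `2^depth`.
#' @param model a [weedseg] model.
#' @return H x W x C array of class probabilities (per-pixel sums equal 1).
#' @export
unet_forward_probs <- function(image, model) {
  x <- if (inherits(image, "multispectral_image")) image$pixels else image
  softmax3(unet_forward(x, model$unet, model$unet_config)$logits)
}

#' PCA reduction of a VIS/NIR pair to three bands
#'
#' Stacks the 16 channels, centres them, projects every pixel onto the top
#' three principal axes of the image's own pixel cloud, and rescales each
#' component to `[0, 1]`. Component signs are fixed by making the
#' largest-magnitude loading of each axis positive, so the reduction is
#' deterministic.
#'
#' @param vis,nir co-registered 8-band [multispectral_image]s.
#' @param n_components number of components kept (3).
#' @return A 3-band `"PCA"` [multispectral_image]; zero-variance components
#'   are flagged in attribute `"degenerate_components"`.
#' @export
pca_reduce <- function(vis, nir, n_components = 3L) {
  stopifnot(inherits(vis, "multispectral_image"),
            inherits(nir, "multispectral_image"))
  d <- dim(vis$pixels)
  if (!identical(d[1:2], dim(nir$pixels)[1:2]))
    stop("VIS and NIR cubes must be co-registered (same size)")
  x <- cbind(matrix(vis$pixels, d[1] * d[2], 8L),
             matrix(nir$pixels, d[1] * d[2], 8L))
  if (sum(apply(x, 2, stats::var) > 1e-12) < n_components)
    stop("fewer than ", n_components, " non-degenerate channels")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pr$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components))
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  scores <- sweep(x, 2, colMeans(x)) %*% rot
  degenerate <- logical(n_components)
  for (j in seq_len(n_components)) {
    rng <- range(scores[, j])
    if (diff(rng) < 1e-12) {
      scores[, j] <- 0
      degenerate[j] <- TRUE
    } else scores[, j] <- (scores[, j] - rng[1]) / diff(rng)
  }
  out <- multispectral_image(array(scores, c(d[1], d[2], n_components)),
                             default_band_centers("PCA"), "PCA")
  attr(out, "degenerate_components") <- degenerate
  out
}
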