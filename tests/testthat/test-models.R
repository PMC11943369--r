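test_that("branch extraction preserves spatial size and separates branch weights", {
  model <- small_fusion_model(seed = 2)
  cube <- random_cube(32, 32, 8, seed = 3)
  fv <- extract_branch_features(cube, "VIS", model)
  expect_equal(dim(fv), c(32, 32, 4))
  nircube <- multispectral_image(cube$pixels, default_band_centers("NIR"), "NIR")
  fn <- extract_branch_features(nircube, "NIR", model)
  expect_false(isTRUE(all.equal(fv, fn)))  # independent weights
  expect_error(extract_branch_features(nircube, "VIS", model), "domain")
  # zero input responds with pure bias propagation, identically across calls
  zero <- multispectral_image(array(0, c(32, 32, 8)),
                              default_band_centers("VIS"), "VIS")
  expect_identical(extract_branch_features(zero, "VIS", model),
                   extract_branch_features(zero, "VIS", model))
})

test_that("attention fusion gates channels multiplicatively in (0,1)", {
  model <- small_fusion_model(seed = 4)
  fv <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  fn <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  fused <- fuse_features(fv, fn, model)
  expect_equal(dim(fused), c(16, 16, 8))
  w <- attr(fused, "attention")
  expect_length(w, 8)
  expect_true(all(w > 0 & w < 1))
  # zeroed input channel stays zero after gating
  fv0 <- fv; fv0[, , 2] <- 0
  fused0 <- fuse_features(fv0, fn, model)
  expect_true(all(fused0[, , 2] == 0))
  expect_error(fuse_features(fv, array(0, c(8, 8, 4)), model), "mismatch")
})

test_that("reconstruction returns a clamped 8-band fused image deterministically", {
  model <- small_fusion_model(seed = 5)
  fused <- array(rnorm(16 * 16 * 8, sd = 2), c(16, 16, 8))
  out <- reconstruct_fused(fused, model)
  expect_s3_class(out, "multispectral_image")
  expect_equal(out$domain_tag, "FUSED")
  expect_equal(dim(out$pixels), c(16, 16, 8))
  expect_gte(min(out$pixels), 0)
  expect_lte(max(out$pixels), 1)
  expect_identical(out$pixels, reconstruct_fused(fused, model)$pixels)
})

test_that("the zero-padded U-Net outputs valid probability fields of input size", {
  model <- small_fusion_model(seed = 6)
  x <- random_cube(32, 48, 8, seed = 7)
  probs <- unet_forward_probs(x, model)
  expect_equal(dim(probs), c(32, 48, 3))
  sums <- probs[, , 1] + probs[, , 2] + probs[, , 3]
  expect_lt(max(abs(sums - 1)), 1e-5)
  # indivisible size is rejected (depth 2 -> multiples of 4)
  bad <- array(runif(30 * 32 * 8), c(30, 32, 8))
  expect_error(unet_forward_probs(bad, model), "divisible")
  expect_error(unet_forward_probs(array(runif(32 * 32 * 5), c(32, 32, 5)),
                                  model), "channels")
})

test_that("all three networks preserve spatial dimensions on random compliant shapes", {
  model <- small_fusion_model(seed = 8)
  set.seed(9)
  for (i in 1:20) {
    h <- sample(c(16, 24, 32, 40), 1)
    w <- sample(c(16, 24, 32, 40), 1)
    vis <- array(runif(h * w * 8), c(h, w, 8))
    nir <- array(runif(h * w * 8), c(h, w, 8))
    pf <- weedseg:::pifnet_forward(vis, nir, model$pif)
    expect_equal(dim(pf$fused)[1:2], c(h, w))
    probs <- unet_forward_probs(pf$fused, model)
    expect_equal(dim(probs)[1:2], c(h, w))
    sums <- probs[, , 1] + probs[, , 2] + probs[, , 3]
    expect_lt(max(abs(sums - 1)), 1e-5)
  }
})

test_that("fusion genuinely uses both branches", {
  model <- small_fusion_model(seed = 10)
  vis <- array(runif(16 * 16 * 8), c(16, 16, 8))
  nir <- array(runif(16 * 16 * 8), c(16, 16, 8))
  full <- weedseg:::pifnet_forward(vis, nir, model$pif)$fused
  gated <- weedseg:::pifnet_forward(vis, array(0, c(16, 16, 8)),
                                    model$pif)$fused
  expect_gt(sqrt(sum((full - gated)^2)), 0)
})

test_that("segmentation loss is zero iff one-hot correct and matches closed forms", {
  truth <- matrix(0L, 8, 8); truth[1:4, ] <- 1L  # balanced half-plane, C = 2
  onehot <- array(0, c(8, 8, 2))
  onehot[, , 1] <- (truth == 0) + 0
  onehot[, , 2] <- (truth == 1) + 0
  expect_lt(segmentation_loss(onehot, truth, c(1, 0)), 1e-12)  # Dice part
  expect_lt(segmentation_loss(onehot, truth, c(1, 1)), 1e-6)   # + CE at p=1
  # uniform 1/2 prediction on the balanced mask: soft Dice = 0.5
  unif <- array(0.5, c(8, 8, 2))
  expect_equal(segmentation_loss(unif, truth, c(1, 0)), 0.5)
  expect_equal(segmentation_loss(unif, truth, c(0, 1)), log(2), tolerance = 1e-9)
  # non-negativity on random inputs
  set.seed(14)
  for (i in 1:100) {
    l <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    probs <- weedseg:::softmax3(l)
    tr <- matrix(sample(0:2, 64, TRUE), 8, 8)
    expect_gte(segmentation_loss(probs, tr), 0)
  }
  expect_error(segmentation_loss(unif, matrix(5L, 8, 8)), "exceeds")
})

test_that("PCA reduction recovers planted subspaces and maximizes variance", {
  set.seed(15)
  # planted: pixels lie in a 3-dim subspace of the 16 channels (plus tiny noise)
  n <- 32 * 32
  basis <- qr.Q(qr(matrix(rnorm(16 * 3), 16, 3)))
  scores <- matrix(rnorm(n * 3, sd = c(3, 2, 1)), n, 3, byrow = TRUE)
  x <- scores %*% t(basis) + matrix(rnorm(n * 16, sd = 1e-4), n, 16)
  x <- (x - min(x)) / diff(range(x))
  vis <- multispectral_image(array(x[, 1:8], c(32, 32, 8)),
                             default_band_centers("VIS"), "VIS")
  nir <- multispectral_image(array(x[, 9:16], c(32, 32, 8)),
                             default_band_centers("NIR"), "NIR")
  red <- pca_reduce(vis, nir)
  expect_equal(red$domain_tag, "PCA")
  expect_equal(dim(red$pixels), c(32, 32, 3))
  expect_gte(min(red$pixels), 0); expect_lte(max(red$pixels), 1)
  # principal angle between recovered and planted subspaces ~ 0
  xm <- cbind(matrix(vis$pixels, n, 8), matrix(nir$pixels, n, 8))
  rot <- stats::prcomp(xm, center = TRUE)$rotation[, 1:3]
  ang <- acos(pmin(1, svd(crossprod(basis, rot))$d))
  expect_lt(max(ang), 1e-3)
  # eigen-optimality: top-3 PCs explain at least as much variance as any
  # 3 raw channels
  pr <- stats::prcomp(xm, center = TRUE)
  best_raw <- max(combn(16, 3, function(j) sum(apply(xm[, j], 2, var))))
  expect_gte(sum(pr$sdev[1:3]^2) + 1e-9, best_raw)
  # determinism incl. sign convention
  expect_identical(red$pixels, pca_reduce(vis, nir)$pixels)
  # degenerate rank-1 input errors
  flat <- array(0.5, c(32, 32, 8))
  v1 <- multispectral_image(flat, default_band_centers("VIS"), "VIS")
  n1 <- multispectral_image(flat, default_band_centers("NIR"), "NIR")
  expect_error(pca_reduce(v1, n1), "non-degenerate")
})

test_that("joint loss optimization overfits a single fixed batch", {
  set.seed(16)
  sc <- generate_scene(scene_spec(height = 32, width = 32, n_plants = 2,
                                  n_weeds = 1, blob_radius_range = c(4, 8),
                                  seed = 900))
  fc <- fusion_config(branch_channels = 8)
  uc <- unet_config(in_channels = 8, depth = 2, base_filters = 8)
  pif <- weedseg:::pifnet_init(fc)
  up <- weedseg:::unet_init(uc)
  st_p <- weedseg:::adam_init(pif); st_u <- weedseg:::adam_init(up)
  lab <- sc$labels$labels
  first_loss <- NA; acc <- 0
  for (step in 1:50) {
    pf <- weedseg:::pifnet_forward(sc$vis$pixels, sc$nir$pixels, pif)
    uf <- weedseg:::unet_forward(pf$fused, up, uc)
    lg <- weedseg:::loss_and_grad(uf$logits, lab, 3)
    if (step == 1) first_loss <- lg$loss
    acc <- lg$accuracy
    ub <- weedseg:::unet_backward(lg$dlogits, uf$cache, up, uc)
    pb <- weedseg:::pifnet_backward(ub$dx, pf$cache, pif)
    r <- weedseg:::adam_step(up, ub$grads, st_u, 0.005)
    up <- r$params; st_u <- r$state
    r <- weedseg:::adam_step(pif, pb$grads, st_p, 0.005)
    pif <- r$params; st_p <- r$state
    if (acc > 0.99) break
  }
  expect_gt(acc, 0.99)
  expect_lt(lg$loss, first_loss)
})
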