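test_that("sRGB to Lab matches the standard D65 closed form and inverts", {
  rgb <- array(0, c(1, 3, 3))
  rgb[1, 1, ] <- c(1, 1, 1)    # white
  rgb[1, 2, ] <- c(0, 0, 0)    # black
  rgb[1, 3, ] <- c(0.5, 0.5, 0.5)  # mid grey
  lab <- srgb_to_lab(rgb)
  expect_equal(lab[1, 1, 1], 100, tolerance = 1e-3)
  expect_lt(max(abs(lab[1, 1, 2:3])), 0.5)
  expect_equal(lab[1, 2, 1], 0, tolerance = 1e-6)
  expect_equal(lab[1, 3, 1], 53.39, tolerance = 1e-2)
  expect_lt(max(abs(lab[1, 3, 2:3])), 0.05)

  # grDevices::convertColor as the independent oracle on random colours
  set.seed(3)
  cols <- array(runif(60), c(20, 1, 3))
  ours <- srgb_to_lab(cols)
  ref <- grDevices::convertColor(matrix(cols, 20, 3), "sRGB", "Lab")
  expect_equal(matrix(ours, 20, 3), unname(ref), tolerance = 0.3)

  # round trip
  back <- lab_to_srgb(ours)
  expect_equal(back, cols, tolerance = 1e-3)
})

test_that("k-means on chroma recovers a planted partition exactly", {
  set.seed(8)
  # three tight, well-separated chroma blobs on a 30x30 image
  centers <- rbind(c(-40, 30), c(5, -25), c(35, 45))
  assign_true <- matrix(sample(1:3, 900, TRUE), 30, 30)
  lab <- array(0, c(30, 30, 3))
  lab[, , 1] <- 50
  lab[, , 2] <- centers[assign_true, 1] + rnorm(900, 0, 0.5)
  lab[, , 3] <- centers[assign_true, 2] + rnorm(900, 0, 0.5)
  cl <- kmeans_ab(lab, k = 3, seed = 1)
  # adjusted Rand of 1 <=> identical partitions up to relabelling
  tab <- table(cl$assignments, assign_true)
  expect_equal(sum(apply(tab, 1, max)), 900)
  # centroids in canonical order (ascending a)
  expect_true(all(diff(cl$centroids[, 1]) >= 0))
  # independent oracle: stats::kmeans reaches the same within-cluster SS
  pts <- cbind(as.vector(lab[, , 2]), as.vector(lab[, , 3]))
  ref <- stats::kmeans(pts, 3, nstart = 5)
  expect_equal(cl$wss_trace[length(cl$wss_trace)], ref$tot.withinss,
               tolerance = 1e-6)
})

test_that("k-means is deterministic per seed, rejects degenerate input, and descends", {
  sc <- generate_scene(scene_spec(seed = 31))
  lab <- srgb_to_lab(render_srgb(sc$vis))
  a <- kmeans_ab(lab, 3, seed = 5)
  b <- kmeans_ab(lab, 3, seed = 5)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$centroids, b$centroids)
  # monotone descent of within-cluster sum of squares
  expect_true(all(diff(a$wss_trace) <= 1e-9))
  expect_error(kmeans_ab(lab, 1), "at least 2")
  flat <- array(0, c(16, 16, 3))
  expect_error(kmeans_ab(flat, 2), "degenerate")
})

test_that("cluster-to-class mapping follows greenness with override support", {
  sc <- generate_scene(scene_spec(noise_sd = 0.01, seed = 41))
  ann <- annotate_scene(sc$vis, k = 3, seed = 2)
  expect_gte(pixel_accuracy(ann$labels, sc$labels), 0.95)
  # explicit override table wins
  cl <- ann$clusters
  forced <- clusters_to_classes(cl, override = c(2L, 1L, 0L))
  expect_identical(sort(unique(as.vector(forced$labels))),
                   sort(unique(c(2L, 1L, 0L)[cl$assignments + 1])))
  # k = 2 without override: plant vs soil only
  cl2 <- kmeans_ab(srgb_to_lab(render_srgb(sc$vis)), 2, seed = 2)
  m2 <- clusters_to_classes(cl2)
  expect_true(all(m2$labels %in% c(0L, 1L)))
})

test_that("instance extraction matches 8-connectivity component semantics", {
  # two disjoint plant blobs -> ids 1 and 2 in raster order
  m <- matrix(0L, 20, 20)
  m[2:7, 2:7] <- 1L
  m[12:18, 12:18] <- 1L
  inst <- extract_instances(label_mask(m), min_area = 5)
  expect_identical(inst$instance_class, c(1L, 1L))
  expect_equal(sort(unique(as.vector(inst$instances))), 0:2)
  expect_true(inst$instances[2, 2] == 1L && inst$instances[12, 12] == 2L)

  # touching plant and weed blobs stay separate (components are per class)
  m2 <- matrix(0L, 20, 20)
  m2[2:10, 2:10] <- 1L
  m2[2:10, 11:18] <- 2L
  inst2 <- extract_instances(label_mask(m2), min_area = 5)
  expect_identical(sort(inst2$instance_class), c(1L, 2L))

  # diagonal contact joins a component (8-connectivity); EBImage's 4-connected
  # labeller is the contrasting oracle
  m3 <- matrix(0L, 10, 10)
  m3[cbind(c(2, 3, 4), c(2, 3, 4))] <- 1L
  inst3 <- extract_instances(label_mask(m3), min_area = 1)
  expect_length(inst3$instance_class, 1)
  expect_gt(max(EBImage::bwlabel(m3)), 1)  # 4-connectivity would split it

  # min_area suppression and empty masks
  m4 <- matrix(0L, 10, 10); m4[1, 1] <- 1L
  expect_length(extract_instances(label_mask(m4), min_area = 2)$instance_class, 0)
  expect_length(extract_instances(label_mask(matrix(0L, 8, 8)))$instance_class, 0)
})

test_that("binary masks are disjoint and cover the instance support", {
  sc <- generate_scene(scene_spec(seed = 51))
  inst <- sc$instances
  bm <- binary_masks(inst)
  expect_length(bm, length(inst$instance_class))
  if (length(bm)) {
    areas <- vapply(bm, sum, 1)
    expect_equal(areas, vapply(seq_along(bm),
                               function(i) sum(inst$instances == i), 1))
    acc <- Reduce(`+`, bm)
    expect_true(all(acc <= 1))               # pairwise disjoint
    expect_equal(acc > 0, inst$instances > 0)  # union equals support
  }
  expect_length(binary_masks(instance_mask(matrix(0L, 8, 8), integer(0))), 0)
})

test_that("the full annotation chain recovers noiseless scenes with high Dice", {
  for (s in 1:10) {
    sc <- generate_scene(scene_spec(noise_sd = 0, illumination_gradient = 0,
                                    seed = 600 + s))
    ann <- annotate_scene(sc$vis, k = 3, seed = 1)
    for (cl in 0:2)
      expect_gte(dice(ann$labels$labels == cl, sc$labels$labels == cl), 0.95)
  }
})
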