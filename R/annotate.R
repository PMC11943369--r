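#' sRGB to CIELAB conversion
#'
#' Standard sRGB (IEC 61966-2-1) to CIELAB under the D65 white point and the
#' 2 degree observer. `lab_to_srgb()` is the exact inverse up to clipping.
#'
#' @param rgb a 3-band `"RGB"` [multispectral_image], or an H x W x 3 array
#'   in `[0, 1]`.
#' @return H x W x 3 array with `L` in `[0, 100]` and `a`, `b` chroma planes.
#' @export
srgb_to_lab <- function(rgb) {
  px <- if (inherits(rgb, "multispectral_image")) {
    if (rgb$domain_tag != "RGB") stop("srgb_to_lab expects an RGB image")
    rgb$pixels
  } else rgb
  if (length(dim(px)) != 3L || dim(px)[3L] != 3L)
    stop("srgb_to_lab expects an H x W x 3 array")
  d <- dim(px)
  s <- matrix(px, d[1] * d[2], 3L)
  lin <- ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
  m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(m)
  wp <- c(0.95047, 1.00000, 1.08883)
  t3 <- sweep(xyz, 2, wp, "/")
  delta <- 6 / 29
  f <- ifelse(t3 > delta^3, t3^(1 / 3), t3 / (3 * delta^2) + 4 / 29)
  lab <- cbind(116 * f[, 2] - 16,
               500 * (f[, 1] - f[, 2]),
               200 * (f[, 2] - f[, 3]))
  array(lab, c(d[1], d[2], 3L))
}

#' @rdname srgb_to_lab
#' @param lab H x W x 3 CIELAB array.
#' @export
lab_to_srgb <- function(lab) {
  d <- dim(lab)
  l <- matrix(lab, d[1] * d[2], 3L)
  fy <- (l[, 1] + 16) / 116
  fx <- fy + l[, 2] / 500
  fz <- fy - l[, 3] / 200
  delta <- 6 / 29
  finv <- function(f) ifelse(f > delta, f^3, 3 * delta^2 * (f - 4 / 29))
  wp <- c(0.95047, 1.00000, 1.08883)
  xyz <- cbind(finv(fx) * wp[1], finv(fy) * wp[2], finv(fz) * wp[3])
  minv <- solve(matrix(c(0.4124564, 0.3575761, 0.1804375,
                         0.2126729, 0.7151522, 0.0721750,
                         0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE))
  lin <- xyz %*% t(minv)
  s <- ifelse(lin <= 0.0031308, 12.92 * lin,
              1.055 * pmax(lin, 0)^(1 / 2.4) - 0.055)
  array(clamp01(s), c(d[1], d[2], 3L))
}

# squared Euclidean distances from n points to k centroids (n x k)
dist2_to_centroids <- function(pts, centers) {
  outer(rowSums(pts^2), rep(1, nrow(centers))) -
    2 * pts %*% t(centers) +
    outer(rep(1, nrow(pts)), rowSums(centers^2))
}

# seeded k-means++ initial centres
kmeanspp_init <- function(pts, k) {
  n <- nrow(pts)
  centers <- matrix(0, k, ncol(pts))
  centers[1, ] <- pts[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(pts, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L, ] <- pts[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(pts, 2, centers[j + 1L, ])^2))
  }
  centers
}

#' K-means clustering on the CIELAB a/b chroma plane
#'
#' Lloyd's algorithm restricted to the (a, b) chroma components — lightness
#' is excluded so that clusters follow colour, not illumination. Runs
#' `nstart` seeded k-means++ initializations and keeps the lowest-inertia
#' solution. Iterations never increase the within-cluster sum of squares;
#' the trace is returned in `wss_trace`. Centroids are reported in canonical
#' order (ascending `a`, ties by `b`) with assignments relabelled to match,
#' so results are stable across runs with the same seed.
#'
#' @param lab H x W x 3 CIELAB array from [srgb_to_lab()].
#' @param k number of clusters (>= 2).
#' @param seed integer seed for the initializations.
#' @param max_iter maximum Lloyd iterations per restart.
#' @param nstart number of k-means++ restarts.
#' @return An object of class `cluster_map`: `assignments` (H x W integer
#'   matrix, ids 0..k-1), `centroids` (k x 2 matrix of (a, b)), `k`,
#'   `wss_trace`.
#' @export
kmeans_ab <- function(lab, k = 3L, seed = 0L, max_iter = 100L, nstart = 5L) {
  if (k < 2L) stop("k must be at least 2")
  d <- dim(lab)
  pts <- cbind(as.vector(lab[, , 2]), as.vector(lab[, , 3]))
  if (nrow(unique(pts)) < k)
    stop("degenerate input: fewer distinct chroma values than clusters")
  best <- NULL
  with_local_seed(seed, {
    for (s in seq_len(nstart)) {
      centers <- kmeanspp_init(pts, k)
      wss_trace <- numeric(0)
      assign_old <- integer(0)
      for (it in seq_len(max_iter)) {
        d2 <- dist2_to_centroids(pts, centers)
        assign <- max.col(-d2, ties.method = "first")
        wss_trace <- c(wss_trace, sum(d2[cbind(seq_len(nrow(pts)), assign)]))
        if (identical(assign, assign_old)) break
        assign_old <- assign
        for (j in seq_len(k)) {
          sel <- assign == j
          if (any(sel)) centers[j, ] <- colMeans(pts[sel, , drop = FALSE])
          else centers[j, ] <- pts[which.max(rowSums(d2)), ]  # respawn empty cluster
        }
      }
      inertia <- wss_trace[length(wss_trace)]
      if (is.null(best) || inertia < best$inertia)
        best <- list(assign = assign, centers = centers, inertia = inertia,
                     wss_trace = wss_trace)
    }
  })
  ord <- order(best$centers[, 1], best$centers[, 2])
  relabel <- match(seq_len(k), ord)
  structure(list(assignments = matrix(relabel[best$assign] - 1L, d[1], d[2]),
                 centroids = best$centers[ord, , drop = FALSE],
                 k = as.integer(k),
                 wss_trace = best$wss_trace),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> %d x %d, k = %d, inertia = %.3f\n",
              nrow(x$assignments), ncol(x$assignments), x$k,
              x$wss_trace[length(x$wss_trace)]))
  invisible(x)
}

#' Map chroma clusters to soil/plant/weed classes
#'
#' Vegetation is green, i.e. strongly negative on the CIELAB `a` axis: the
#' cluster with the most negative mean `a` becomes plant, the next most
#' negative becomes weed (when `k >= 3`), and all remaining clusters become
#' soil. An explicit override table replaces the rule entirely.
#'
#' @param clusters a `cluster_map` from [kmeans_ab()].
#' @param override optional integer vector of length `k`: element `j` is the
#'   class id assigned to cluster `j - 1`.
#' @return A [label_mask].
#' @export
clusters_to_classes <- function(clusters, override = NULL) {
  stopifnot(inherits(clusters, "cluster_map"))
  k <- clusters$k
  if (!is.null(override)) {
    if (length(override) != k) stop("override must map every cluster")
    cls <- as.integer(override)
  } else {
    cls <- rep(0L, k)
    ord <- order(clusters$centroids[, 1])
    cls[ord[1]] <- 1L
    if (k >= 3L) cls[ord[2]] <- 2L
  }
  label_mask(matrix(cls[clusters$assignments + 1L],
                    nrow(clusters$assignments), ncol(clusters$assignments)))
}

# Two-pass 8-connectivity connected-component labelling (union-find).
# Returns an integer matrix of component ids in arbitrary order.
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  nxt <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    nb <- integer(0)
    if (c > 1L && lab[r, c - 1L]) nb <- c(nb, lab[r, c - 1L])
    if (r > 1L) {
      if (lab[r - 1L, c]) nb <- c(nb, lab[r - 1L, c])
      if (c > 1L && lab[r - 1L, c - 1L]) nb <- c(nb, lab[r - 1L, c - 1L])
      if (c < w && lab[r - 1L, c + 1L]) nb <- c(nb, lab[r - 1L, c + 1L])
    }
    if (!length(nb)) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[r, c] <- nxt
    } else {
      roots <- vapply(unique(nb), find, 1L)
      keep <- min(roots)
      lab[r, c] <- keep
      for (x in roots) parent[x] <- keep
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, 1L)
  lab[lab > 0L] <- roots[lab[lab > 0L]]
  lab
}

#' Extract instances from a semantic label mask
#'
#' Connected components (8-connectivity) are computed separately within each
#' nonzero class, components below `min_area` pixels are suppressed, and the
#' surviving instances are renumbered in raster order of their first pixel
#' (row-major scan).
#'
#' @param labels a [label_mask].
#' @param min_area minimum component size in pixels (default 25, matching
#'   the smallest blob footprint worth annotating; suppresses speckle).
#' @return An [instance_mask].
#' @export
extract_instances <- function(labels, min_area = 25L) {
  stopifnot(inherits(labels, "label_mask"))
  lm <- labels$labels
  h <- nrow(lm); w <- ncol(lm)
  inst <- matrix(0L, h, w)
  cls_of <- integer(0)
  first_px <- integer(0)
  nxt <- 0L
  raster_index <- t(matrix(seq_len(h * w), w, h))  # row-major scan order
  for (cl in setdiff(sort(unique(as.vector(lm))), 0L)) {
    comp <- label_components8(lm == cl)
    for (id in setdiff(unique(as.vector(comp)), 0L)) {
      sel <- comp == id
      if (sum(sel) < min_area) next
      nxt <- nxt + 1L
      inst[sel] <- nxt
      cls_of[nxt] <- cl
      first_px[nxt] <- min(raster_index[sel])
    }
  }
  if (nxt == 0L)
    return(instance_mask(inst, integer(0)))
  ord <- order(first_px)
  remap <- match(seq_len(nxt), ord)
  inst[inst > 0L] <- remap[inst[inst > 0L]]
  instance_mask(inst, cls_of[ord])
}

#' Per-instance binary masks
#'
#' One binary matrix per instance, pairwise disjoint, whose union equals the
#' nonzero support of the instance map — the single-plant mask format used
#' for building per-plant training examples.
#'
#' @param instances an [instance_mask].
#' @return List of H x W logical matrices, one per instance id.
#' @export
binary_masks <- function(instances) {
  stopifnot(inherits(instances, "instance_mask"))
  lapply(seq_along(instances$instance_class),
         function(id) instances$instances == id)
}

#' Chroma-based ground-truth annotation of a scene
#'
#' The full automated annotation chain: render an sRGB preview of the VIS
#' cube, convert to CIELAB, cluster the a/b chroma plane with K-means, map
#' clusters to classes by greenness, and extract instances.
#'
#' @param vis an 8-band `"VIS"` [multispectral_image].
#' @param k number of chroma clusters.
#' @param seed seed for the clustering initialization.
#' @param min_area minimum instance area in pixels.
#' @param override optional cluster-to-class override table.
#' @return List with `labels` ([label_mask]), `instances`
#'   ([instance_mask]) and `clusters` (`cluster_map`).
#' @export
annotate_scene <- function(vis, k = 3L, seed = 0L, min_area = 25L,
                           override = NULL) {
  rgb <- render_srgb(vis)
  lab <- srgb_to_lab(rgb)
  cl <- kmeans_ab(lab, k = k, seed = seed)
  labels <- clusters_to_classes(cl, override = override)
  list(labels = labels,
       instances = extract_instances(labels, min_area = min_area),
       clusters = cl)
}
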