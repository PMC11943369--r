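#' Spectral reflectance signatures
#'
#' A signature describes the mean reflectance of one class in the 16 broad
#' bands (8 VIS then 8 NIR) and its per-band standard deviation. The bundled
#' defaults are synthetic stand-ins shaped by vegetation optics: green plants
#' reflect little in the red, peak near 550 nm, and jump across the red edge
#' into the NIR (chlorophyll); weeds carry an intermediate NIR level and a
#' yellow-shifted chroma; soil is nearly flat around 0.3 with a gentle upward
#' tilt (brown).
#'
#' @param class_id integer class id (0 soil, 1 plant, 2 weed).
#' @param mean_reflectance length-16 means in `[0, 1]` (8 VIS then 8 NIR).
#' @param sd_reflectance length-16 non-negative standard deviations.
#' @return An object of class `spectral_signature`.
#' @export
spectral_signature <- function(class_id, mean_reflectance, sd_reflectance) {
  stopifnot(length(mean_reflectance) == 16L, length(sd_reflectance) == 16L,
            all(mean_reflectance >= 0 & mean_reflectance <= 1),
            all(sd_reflectance >= 0))
  structure(list(class_id = as.integer(class_id),
                 mean_reflectance = as.numeric(mean_reflectance),
                 sd_reflectance = as.numeric(sd_reflectance)),
            class = "spectral_signature")
}

#' @rdname spectral_signature
#' @details `default_signatures()` returns the three default signatures
#'   (soil, plant, weed). Every pair differs by at least
#'   `2 * (sd_i + sd_j)` in at least one band, so classes remain separable
#'   under the generator's noise model.
#' @export
default_signatures <- function() {
  sd16 <- rep(0.02, 16)
  soil  <- c(seq(0.24, 0.38, length.out = 8), rep(0.32, 8))
  plant <- c(0.05, 0.06, 0.08, 0.12, 0.20, 0.24, 0.14, 0.08,
             seq(0.62, 0.76, length.out = 8))
  weed  <- c(0.06, 0.07, 0.09, 0.13, 0.20, 0.26, 0.24, 0.18,
             seq(0.42, 0.52, length.out = 8))
  list(spectral_signature(0L, soil, sd16),
       spectral_signature(1L, plant, sd16),
       spectral_signature(2L, weed, sd16))
}

#' Check pairwise separability of a signature set
#'
#' @param signatures list of [spectral_signature] objects.
#' @return `TRUE` if every pair differs by `>= 2 * (sd_i + sd_j)` in at
#'   least one band, else `FALSE`.
#' @export
signatures_separable <- function(signatures) {
  n <- length(signatures)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    gap <- abs(signatures[[i]]$mean_reflectance - signatures[[j]]$mean_reflectance)
    need <- 2 * (signatures[[i]]$sd_reflectance + signatures[[j]]$sd_reflectance)
    if (!any(gap >= need)) return(FALSE)
  }
  TRUE
}

#' Synthetic scene specification
#'
#' Parameters of one generated soil/plant/weed scene. Heights and widths must
#' be multiples of 16 so that generated images divide both the MSFA tile and
#' the pooling pyramid of the segmentation network.
#'
#' @param height,width scene size in pixels (multiples of 16).
#' @param n_plants,n_weeds number of plant / weed blobs.
#' @param blob_radius_range length-2 range of blob radii in pixels.
#' @param overlap_allowed may blobs overlap (later blobs occlude earlier)?
#' @param noise_sd additive Gaussian sensor noise sd (reflectance units).
#' @param illumination_gradient maximum multiplicative slope of the planar
#'   illumination field across the frame (0 = flat).
#' @param signatures list of class [spectral_signature]s.
#' @param seed integer seed; scenes are bit-reproducible per seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(height = 64L, width = 64L, n_plants = 3L, n_weeds = 2L,
                       blob_radius_range = c(6, 14), overlap_allowed = TRUE,
                       noise_sd = 0.02, illumination_gradient = 0.1,
                       signatures = default_signatures(), seed = 0L) {
  if (height %% 16L || width %% 16L)
    stop("height and width must be multiples of 16")
  stopifnot(n_plants >= 0L, n_weeds >= 0L, noise_sd >= 0,
            illumination_gradient >= 0, length(blob_radius_range) == 2L)
  if (!signatures_separable(signatures))
    stop("signatures violate the pairwise separability guard")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_plants = as.integer(n_plants), n_weeds = as.integer(n_weeds),
                 blob_radius_range = blob_radius_range,
                 overlap_allowed = isTRUE(overlap_allowed),
                 noise_sd = noise_sd,
                 illumination_gradient = illumination_gradient,
                 signatures = signatures, seed = as.integer(seed)),
            class = "scene_spec")
}

# Boolean mask of one perturbed ellipse: a low-frequency radial modulation
# gives leaf-like curved boundaries rather than perfect conics.
blob_mask <- function(h, w, cy, cx, ry, rx, theta0, amp) {
  r <- matrix(seq_len(h), h, w) - cy
  c <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  ang <- atan2(r, c)
  rad <- 1
  for (k in 2:4)
    rad <- rad + amp[k - 1] * cos(k * (ang + theta0))
  u <- (c * cos(theta0) + r * sin(theta0)) / rx
  v <- (-c * sin(theta0) + r * cos(theta0)) / ry
  (u * u + v * v) <= rad * rad
}

#' Generate a synthetic co-registered VIS/NIR scene
#'
#' Plants are placed first, then weeds; when blobs overlap, later blobs
#' occlude earlier ones and the label/instance masks follow the final
#' geometry. Per-pixel reflectance is the class signature mean (plus a small
#' per-instance offset bounded by the signature sd), multiplied by a planar
#' illumination field, plus additive Gaussian sensor noise, clipped to
#' `[0, 1]`. VIS and NIR cubes are perfectly co-registered by construction.
#'
#' @param spec a [scene_spec].
#' @return A list with elements `vis` and `nir` ([multispectral_image]s),
#'   `labels` ([label_mask]) and `instances` ([instance_mask]).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_local_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    labels <- matrix(0L, h, w)
    instances <- matrix(0L, h, w)
    classes <- c(rep(1L, spec$n_plants), rep(2L, spec$n_weeds))
    placed_class <- integer(0)
    next_id <- 0L
    for (cl in classes) {
      ok <- FALSE
      for (try in 1:50) {
        ry <- stats::runif(1, spec$blob_radius_range[1], spec$blob_radius_range[2])
        rx <- stats::runif(1, spec$blob_radius_range[1], spec$blob_radius_range[2])
        cy <- stats::runif(1, 1 + 0.5 * ry, h - 0.5 * ry)
        cx <- stats::runif(1, 1 + 0.5 * rx, w - 0.5 * rx)
        th <- stats::runif(1, 0, pi)
        amp <- pmin(pmax(stats::rnorm(3, 0, 0.06), -0.15), 0.15)
        m <- blob_mask(h, w, cy, cx, ry, rx, th, amp)
        if (!any(m)) next
        if (!spec$overlap_allowed && any(instances[m] > 0L)) next
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place blob: scene specification too crowded")
      next_id <- next_id + 1L
      labels[m] <- cl
      instances[m] <- next_id
      placed_class <- c(placed_class, cl)
    }
    # occlusion may erase earlier blobs entirely; keep ids consecutive
    kept <- sort(unique(instances[instances > 0L]))
    remap <- integer(next_id)
    remap[kept] <- seq_along(kept)
    instances[instances > 0L] <- remap[instances[instances > 0L]]
    placed_class <- placed_class[kept]

    gx <- stats::runif(1, -spec$illumination_gradient, spec$illumination_gradient)
    gy <- stats::runif(1, -spec$illumination_gradient, spec$illumination_gradient)
    illum <- 1 + gy * (matrix(seq_len(h), h, w) - (h + 1) / 2) / h +
                 gx * (matrix(seq_len(w), h, w, byrow = TRUE) - (w + 1) / 2) / w

    mu <- t(vapply(spec$signatures, function(s) s$mean_reflectance, numeric(16)))
    sdm <- t(vapply(spec$signatures, function(s) s$sd_reflectance, numeric(16)))
    # one bounded spectral offset per instance (biological variability);
    # soil keeps the exact signature mean
    n_inst <- length(placed_class)
    offsets <- matrix(0, n_inst + 1L, 16L)
    if (n_inst > 0) {
      raw <- matrix(stats::rnorm(n_inst * 16L, 0, 1), n_inst, 16L)
      for (i in seq_len(n_inst)) {
        s <- 0.5 * sdm[placed_class[i] + 1L, ]
        offsets[i + 1L, ] <- pmin(pmax(raw[i, ] * s, -2 * s), 2 * s)
      }
    }
    cube <- array(0, c(h, w, 16L))
    cls_idx <- as.vector(labels) + 1L
    inst_idx <- as.vector(instances) + 1L
    for (b in 1:16) {
      base <- mu[cls_idx, b] + offsets[inst_idx, b]
      val <- base * as.vector(illum)
      if (spec$noise_sd > 0)
        val <- val + stats::rnorm(h * w, 0, spec$noise_sd)
      cube[, , b] <- clamp01(matrix(val, h, w))
    }
    list(vis = multispectral_image(cube[, , 1:8, drop = FALSE],
                                   default_band_centers("VIS"), "VIS"),
         nir = multispectral_image(cube[, , 9:16, drop = FALSE],
                                   default_band_centers("NIR"), "NIR"),
         labels = label_mask(labels),
         instances = instance_mask(instances, placed_class))
  })
}

#' sRGB rendering weights over the 8 visible bands
#'
#' Gaussian responses peaking near 600 (R), 550 (G) and 450 nm (B) with a
#' 40 nm width, rows normalized to sum to 1 (so constant cubes render to the
#' same constant grey).
#'
#' @param band_centers_nm VIS band centres.
#' @return 3 x 8 non-negative matrix with unit row sums.
#' @export
srgb_weights <- function(band_centers_nm = default_band_centers("VIS")) {
  peaks <- c(R = 600, G = 550, B = 450)
  w <- t(vapply(peaks, function(p)
    exp(-((band_centers_nm - p)^2) / (2 * 40^2)), numeric(length(band_centers_nm))))
  w / rowSums(w)
}

#' Render an sRGB preview of a VIS cube
#'
#' Feeds the chroma-based annotation pipeline, which expects an sRGB image.
#'
#' @param vis an 8-band `"VIS"` [multispectral_image].
#' @return A 3-band `"RGB"` [multispectral_image].
#' @export
render_srgb <- function(vis) {
  stopifnot(inherits(vis, "multispectral_image"))
  if (vis$domain_tag != "VIS") stop("render_srgb expects a VIS cube")
  d <- dim(vis$pixels)
  w <- srgb_weights(vis$band_centers_nm)
  px <- matrix(vis$pixels, d[1] * d[2], d[3]) %*% t(w)
  multispectral_image(clamp01(array(px, c(d[1], d[2], 3L))),
                      default_band_centers("RGB"), "RGB")
}

#' Generate a synthetic benchmark dataset
#'
#' A list of scenes with train/val/test tags, used throughout the package's
#' examples and evaluation harness. Defaults give 40 training, 8 validation
#' and 8 test scenes of 64 x 64 pixels with sensor noise sd 0.02 — small
#' enough to train the fusion pipeline on a single CPU in minutes.
#'
#' @param n_train,n_val,n_test scene counts per split.
#' @param height,width scene size.
#' @param noise_sd sensor noise sd passed to each [scene_spec].
#' @param seed integer; scene `i` uses seed `seed * 10000 + i`.
#' @param ... further arguments forwarded to [scene_spec()].
#' @return List with elements `scenes` (list of [generate_scene()] outputs)
#'   and `split` (character vector of tags).
#' @export
make_benchmark <- function(n_train = 40L, n_val = 8L, n_test = 8L,
                           height = 64L, width = 64L, noise_sd = 0.02,
                           seed = 0L, ...) {
  n <- n_train + n_val + n_test
  scenes <- lapply(seq_len(n), function(i)
    generate_scene(scene_spec(height = height, width = width,
                              noise_sd = noise_sd,
                              seed = (seed * 10000L + i) %% .Machine$integer.max,
                              ...)))
  split <- c(rep("train", n_train), rep("val", n_val), rep("test", n_test))
  list(scenes = scenes, split = split)
}
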