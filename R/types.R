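#' Domain containers for multispectral segmentation
#'
#' A `multispectral_image` is an H x W x B reflectance cube in `[0, 1]` with
#' band centre wavelengths (nm) and a domain tag identifying what the cube
#' holds: `"VIS"` / `"NIR"` (8-band camera cubes), `"FUSED"` (8-band fused
#' output of the fusion network), `"RGB"` (3-band rendering) or `"PCA"`
#' (3-band principal-component reduction).
#'
#' @param pixels numeric array of dimension `c(H, W, B)` with finite values in
#'   `[0, 1]`.
#' @param band_centers_nm numeric vector of length `B`; band centre
#'   wavelengths in nanometres (arbitrary component indices for `"PCA"`).
#' @param domain_tag one of `"VIS"`, `"NIR"`, `"FUSED"`, `"RGB"`, `"PCA"`.
#' @return An object of class `multispectral_image`.
#' @export
multispectral_image <- function(pixels, band_centers_nm, domain_tag) {
  domain_tag <- match.arg(domain_tag, c("VIS", "NIR", "FUSED", "RGB", "PCA"))
  if (length(dim(pixels)) != 3L)
    stop("`pixels` must be an H x W x B array")
  if (!all(is.finite(pixels)))
    stop("pixel values must be finite")
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop("pixel values must lie in [0, 1]")
  b <- dim(pixels)[3L]
  if (length(band_centers_nm) != b)
    stop("length(band_centers_nm) must equal the number of bands")
  expected <- c(VIS = 8L, NIR = 8L, FUSED = 8L, RGB = 3L, PCA = 3L)[domain_tag]
  if (b != expected)
    stop(sprintf("domain '%s' requires %d bands, got %d", domain_tag, expected, b))
  structure(
    list(pixels = pixels, band_centers_nm = as.numeric(band_centers_nm),
         domain_tag = domain_tag),
    class = "multispectral_image")
}

#' @export
print.multispectral_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<multispectral_image> %s  %d x %d pixels, %d band(s)\n",
              x$domain_tag, d[1], d[2], d[3]))
  cat("  band centres (nm):", paste(round(x$band_centers_nm), collapse = ", "), "\n")
  cat(sprintf("  value range: [%.4f, %.4f]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.multispectral_image <- function(x) dim(x$pixels)

#' Default band centre wavelengths
#'
#' Eight broad bands per camera: the visible set spans 425-600 nm and the
#' near-infrared set 710-885 nm, matching the end points of the simulated
#' acquisition system.
#'
#' @param domain_tag `"VIS"`, `"NIR"`, `"RGB"` or `"FUSED"`.
#' @return Numeric vector of band centres in nm.
#' @export
default_band_centers <- function(domain_tag) {
  switch(match.arg(domain_tag, c("VIS", "NIR", "RGB", "FUSED", "PCA")),
         VIS   = seq(425, 600, length.out = 8),
         NIR   = seq(710, 885, length.out = 8),
         FUSED = seq(425, 600, length.out = 8),
         RGB   = c(600, 550, 450),
         PCA   = c(1, 2, 3))
}

#' Per-pixel class label mask
#'
#' @param labels integer matrix of class ids; id 0 is soil/background.
#' @param class_names ordered class names, index 1 corresponding to id 0.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, class_names = c("soil", "plant", "weed")) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (any(labels < 0L) || any(labels >= length(class_names)))
    stop("labels must lie in 0 .. length(class_names) - 1")
  structure(list(labels = labels, class_names = class_names),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d, classes: %s\n",
              nrow(x$labels), ncol(x$labels),
              paste(x$class_names, collapse = "/")))
  print(table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                     labels = x$class_names)))
  invisible(x)
}

#' Per-pixel instance mask
#'
#' @param instances integer matrix; 0 is background, instance ids are
#'   consecutive starting at 1.
#' @param instance_class integer vector; element `i` is the class id of
#'   instance `i` (must be nonzero).
#' @return An object of class `instance_mask`.
#' @export
instance_mask <- function(instances, instance_class) {
  instances <- matrix(as.integer(instances), nrow(instances), ncol(instances))
  ids <- sort(unique(instances[instances > 0L]))
  n <- length(instance_class)
  if (length(ids) && !identical(ids, seq_len(n)))
    stop("instance ids must be consecutive 1..n and all present")
  if (any(instance_class == 0L))
    stop("every instance must map to a nonzero class id")
  structure(list(instances = instances,
                 instance_class = as.integer(instance_class)),
            class = "instance_mask")
}

#' @export
print.instance_mask <- function(x, ...) {
  cat(sprintf("<instance_mask> %d x %d, %d instance(s)\n",
              nrow(x$instances), ncol(x$instances), length(x$instance_class)))
  invisible(x)
}

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All package-level determinism goes through this.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
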