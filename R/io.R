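#' Read a multiband image cube from a multi-page TIFF
#'
#' Each TIFF page holds one band, in ascending wavelength. Stored integer
#' values are rescaled to reflectance in `[0, 1]`.
#'
#' @param path path to a multi-page TIFF file.
#' @param domain_tag `"VIS"`, `"NIR"`, `"FUSED"` (8 bands expected) or
#'   `"RGB"` (3 bands).
#' @param band_centers_nm optional band centres; defaults per domain.
#' @return A [multispectral_image].
#' @export
read_multiband <- function(path, domain_tag,
                           band_centers_nm = default_band_centers(domain_tag)) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] != 1L)
        stop("unsupported sample format: multi-channel TIFF page")
      p <- p[, , 1L]
    }
    p
  })
  expected <- c(VIS = 8L, NIR = 8L, FUSED = 8L, RGB = 3L)[
    match.arg(domain_tag, c("VIS", "NIR", "FUSED", "RGB"))]
  if (length(pages) != expected)
    stop(sprintf("expected %d band planes for domain '%s', found %d",
                 expected, domain_tag, length(pages)))
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("plane-size mismatch between TIFF pages")
  cube <- array(unlist(pages, use.names = FALSE),
                c(dims[1, 1], dims[2, 1], length(pages)))
  multispectral_image(clamp01(cube), band_centers_nm, domain_tag)
}

#' Write a multiband image cube as a 16-bit multi-page TIFF
#'
#' Lossless up to 16-bit quantization: [read_multiband()] inverts it within
#' 1/65535 per pixel.
#'
#' @param image a [multispectral_image].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_multiband <- function(image, path) {
  stopifnot(inherits(image, "multispectral_image"))
  pages <- lapply(seq_len(dim(image$pixels)[3L]),
                  function(b) image$pixels[, , b])
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write TIFF: ", path)
  invisible(path)
}

#' Read / write class or instance masks as single-channel PNG
#'
#' Ids are stored in the 8-bit payload (ids above 255 are rejected), so the
#' files stay raw integer masks readable by any viewer.
#'
#' @param mask a [label_mask] or [instance_mask]; `write_mask` stores its
#'   integer matrix.
#' @param path PNG file path.
#' @return `read_mask` returns an integer matrix of ids.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "label_mask")) mask$labels
       else if (inherits(mask, "instance_mask")) mask$instances
       else matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (max(m) > 255L) stop("mask ids above 255 are not supported by the PNG store")
  png::writePNG(m / 255, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Dataset manifests
#'
#' A manifest lists, per scene, the VIS cube, NIR cube and mask files
#' (relative to `root`) together with a split tag in
#' `{train, val, test, unassigned}`.
#'
#' @param records data frame with columns `scene_id`, `vis`, `nir`, `mask`
#'   and optionally `split`.
#' @param root directory the paths are relative to.
#' @return An object of class `dataset_manifest`.
#' @export
dataset_manifest <- function(records, root = ".") {
  stopifnot(is.data.frame(records),
            all(c("scene_id", "vis", "nir", "mask") %in% names(records)))
  if (is.null(records$split)) records$split <- "unassigned"
  if (!all(records$split %in% c("train", "val", "test", "unassigned")))
    stop("split tags must be train/val/test/unassigned")
  structure(list(records = records, root = root), class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest> %d record(s), root: %s\n",
              nrow(x$records), x$root))
  print(table(x$records$split))
  invisible(x)
}

#' @rdname dataset_manifest
#' @param manifest a `dataset_manifest`.
#' @param path YAML file path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  yaml::write_yaml(list(root = manifest$root,
                        records = lapply(seq_len(nrow(manifest$records)),
                                         function(i) as.list(manifest$records[i, ]))),
                   path)
  invisible(path)
}

#' @rdname dataset_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  recs <- do.call(rbind, lapply(y$records, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  dataset_manifest(recs, root = y$root)
}

#' @rdname dataset_manifest
#' @details `resolve_manifest()` checks that every referenced file exists
#'   under `root` and errors otherwise.
#' @export
resolve_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  paths <- file.path(manifest$root,
                     unlist(manifest$records[c("vis", "nir", "mask")]))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("manifest references missing file(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  invisible(manifest)
}

#' Deterministic train/validation/test split
#'
#' Validation and test sizes are `round(n * fraction)`; the remainder goes to
#' the training split, so held-out splits never exceed their nominal
#' fractions. Assignment is a seeded permutation: the same seed always yields
#' the same split.
#'
#' @param manifest a [dataset_manifest].
#' @param fractions length-3 vector `(train, val, test)` summing to 1.
#' @param seed integer seed controlling the permutation.
#' @return The manifest with `split` tags assigned.
#' @export
split_dataset <- function(manifest, fractions = c(0.70, 0.15, 0.15), seed = 0L) {
  stopifnot(inherits(manifest, "dataset_manifest"), length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  n <- nrow(manifest$records)
  if (n < 3L) stop("need at least 3 records to split")
  n_val <- round(n * fractions[2])
  n_test <- round(n * fractions[3])
  n_train <- n - n_val - n_test
  perm <- with_local_seed(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  if (n_val) split[perm[n_train + seq_len(n_val)]] <- "val"
  if (n_test) split[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  manifest$records$split <- split
  manifest
}
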