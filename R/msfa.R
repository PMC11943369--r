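#' Multispectral filter array (MSFA) pattern
#'
#' A snapshot multispectral camera samples one band per pixel through a
#' periodic mosaic of spectral filters. The pattern is a small tile of band
#' indices (0-7), each appearing exactly once, repeated over the sensor.
#' The physical filter arrangement of the camera is not public; the default
#' is the smallest rectangular tile holding 8 distinct filters, a 4 x 2 tile
#' in row-major band order.
#'
#' @param tile integer matrix containing each of 0..7 exactly once.
#' @return An object of class `msfa_pattern`.
#' @export
msfa_pattern <- function(tile = matrix(0:7, nrow = 4, ncol = 2, byrow = TRUE)) {
  tile <- matrix(as.integer(tile), nrow(tile), ncol(tile))
  if (length(tile) != 8L || !identical(sort(as.vector(tile)), 0:7))
    stop("tile must contain each band index 0..7 exactly once")
  structure(list(tile = tile, tile_shape = dim(tile)), class = "msfa_pattern")
}

# band index (1-based) sampled at each pixel of an H x W frame
pattern_band_matrix <- function(pattern, h, w) {
  th <- pattern$tile_shape[1]; tw <- pattern$tile_shape[2]
  pattern$tile[cbind(rep((seq_len(h) - 1L) %% th + 1L, times = w),
                     rep((seq_len(w) - 1L) %% tw + 1L, each = h))] + 1L
}

#' Simulate snapshot MSFA capture
#'
#' Produces the raw single-plane frame a snapshot camera would record: pixel
#' `(r, c)` holds the reflectance of the band assigned to that position by
#' the periodic pattern. No interpolation is involved.
#'
#' @param image an 8-band [multispectral_image] (`VIS` or `NIR`).
#' @param pattern an [msfa_pattern].
#' @return An object of class `mosaic_image` with fields `pixels` (H x W
#'   matrix), `pattern` and `domain_tag`.
#' @export
msfa_mosaic <- function(image, pattern = msfa_pattern()) {
  stopifnot(inherits(image, "multispectral_image"),
            inherits(pattern, "msfa_pattern"))
  d <- dim(image$pixels)
  if (d[3L] != 8L) stop("MSFA capture requires an 8-band cube")
  if (d[1L] %% pattern$tile_shape[1] != 0L ||
      d[2L] %% pattern$tile_shape[2] != 0L)
    stop("image size must be a multiple of the MSFA tile")
  bidx <- pattern_band_matrix(pattern, d[1L], d[2L])
  px <- matrix(image$pixels[cbind(rep(seq_len(d[1L]), times = d[2L]),
                                  rep(seq_len(d[2L]), each = d[1L]),
                                  as.vector(bidx))],
               d[1L], d[2L])
  structure(list(pixels = px, pattern = pattern,
                 domain_tag = image$domain_tag,
                 band_centers_nm = image$band_centers_nm),
            class = "mosaic_image")
}

#' @export
print.mosaic_image <- function(x, ...) {
  cat(sprintf("<mosaic_image> %s  %d x %d raw frame, %d x %d tile\n",
              x$domain_tag, nrow(x$pixels), ncol(x$pixels),
              x$pattern$tile_shape[1], x$pattern$tile_shape[2]))
  invisible(x)
}

# Separable linear interpolation of a sparse regular lattice onto 1..n.
# `pos` are the sampled coordinates; outside their span the nearest sample is
# replicated (no extrapolation).
interp_weights <- function(pos, n) {
  i1 <- findInterval(seq_len(n), pos)
  i1 <- pmin(pmax(i1, 1L), length(pos) - 1L)
  if (length(pos) == 1L) i1 <- rep(1L, n)
  i2 <- pmin(i1 + 1L, length(pos))
  denom <- pmax(pos[i2] - pos[i1], 1)
  t <- (seq_len(n) - pos[i1]) / denom
  t <- pmin(pmax(t, 0), 1)
  list(i1 = i1, i2 = i2, t = t)
}

#' Demosaic a raw MSFA frame into an 8-band cube
#'
#' Each band is reconstructed from its own sample lattice. At every pixel
#' where a band was physically sampled the raw value is returned exactly
#' (both methods); elsewhere `"bilinear"` interpolates separably between the
#' band's lattice sites (edge values replicated beyond the lattice span) and
#' `"nearest"` copies the nearest site.
#'
#' @param mosaic a `mosaic_image` from [msfa_mosaic()].
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return An 8-band [multispectral_image] of the same height and width.
#' @export
msfa_demosaic <- function(mosaic, method = c("bilinear", "nearest")) {
  stopifnot(inherits(mosaic, "mosaic_image"))
  method <- match.arg(method)
  h <- nrow(mosaic$pixels); w <- ncol(mosaic$pixels)
  tile <- mosaic$pattern$tile
  th <- nrow(tile); tw <- ncol(tile)
  cube <- array(0, c(h, w, 8L))
  for (b in 0:7) {
    off <- which(tile == b, arr.ind = TRUE)[1, ]
    rows <- seq.int(off[1], h, by = th)
    cols <- seq.int(off[2], w, by = tw)
    v <- mosaic$pixels[rows, cols, drop = FALSE]
    if (method == "bilinear") {
      wr <- interp_weights(rows, h)
      vr <- v[wr$i1, , drop = FALSE] * (1 - wr$t) + v[wr$i2, , drop = FALSE] * wr$t
      wc <- interp_weights(cols, w)
      out <- vr[, wc$i1, drop = FALSE] * rep(1 - wc$t, each = h) +
             vr[, wc$i2, drop = FALSE] * rep(wc$t, each = h)
    } else {
      ri <- vapply(seq_len(h), function(r) rows[which.min(abs(rows - r))], 1)
      ci <- vapply(seq_len(w), function(cc) cols[which.min(abs(cols - cc))], 1)
      out <- v[match(ri, rows), match(ci, cols), drop = FALSE]
    }
    cube[, , b + 1L] <- out
  }
  multispectral_image(cube, mosaic$band_centers_nm,
                      if (mosaic$domain_tag %in% c("VIS", "NIR")) mosaic$domain_tag else "VIS")
}
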