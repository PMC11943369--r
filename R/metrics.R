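#' Per-class confusion counts
#'
#' One-vs-rest pixel tallies (TP, FP, FN, TN) per class from exhaustive
#' comparison of a predicted and a reference label mask.
#'
#' @param pred,truth [label_mask]s (or integer matrices) of equal size.
#' @param n_classes total number of classes C.
#' @return Object of class `confusion_counts`: integer matrix C x 4 with
#'   columns TP, FP, FN, TN; rows sum to the pixel count.
#' @export
confusion <- function(pred, truth, n_classes = 3L) {
  p <- if (inherits(pred, "label_mask")) pred$labels else pred
  g <- if (inherits(truth, "label_mask")) truth$labels else truth
  if (!identical(dim(p), dim(g))) stop("shape mismatch between pred and truth")
  if (max(p) >= n_classes || max(g) >= n_classes)
    stop("labels must be < n_classes")
  counts <- t(vapply(seq_len(n_classes) - 1L, function(cl) {
    pp <- p == cl; gg <- g == cl
    c(TP = sum(pp & gg), FP = sum(pp & !gg),
      FN = sum(!pp & gg), TN = sum(!pp & !gg))
  }, integer(4)))
  rownames(counts) <- paste0("class", seq_len(n_classes) - 1L)
  structure(counts, class = "confusion_counts")
}

#' Dice coefficient of two binary masks
#'
#' `2 |S intersect G| / (|S| + |G|)`; when both masks are empty the score is
#' 1 (a perfect prediction of an absent class scores perfectly).
#'
#' @param s,g logical/0-1 matrices of equal size.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(s, g) {
  if (!identical(dim(s), dim(g))) stop("shape mismatch")
  s <- s != 0; g <- g != 0
  denom <- sum(s) + sum(g)
  if (denom == 0) return(1)
  2 * sum(s & g) / denom
}

#' Mean and population standard deviation of per-sample Dice scores
#'
#' The spread uses the population form (divide by N, not N - 1).
#'
#' @param dices numeric vector of per-sample Dice coefficients.
#' @return Named vector `c(mean, sd)`.
#' @export
dice_statistics <- function(dices) {
  if (!length(dices)) stop("need at least one Dice value")
  mu <- mean(dices)
  c(mean = mu, sd = sqrt(mean((dices - mu)^2)))
}

#' Intersection-over-union from confusion counts
#'
#' `TP / (TP + FP + FN)` per class; a class absent from both masks
#' (denominator 0) scores 1 by the both-empty convention. `mean_iou()`
#' averages over all classes.
#'
#' @param counts a [confusion] result.
#' @param class_id class id (0-based).
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(counts, class_id) {
  r <- counts[class_id + 1L, ]
  denom <- r["TP"] + r["FP"] + r["FN"]
  if (denom == 0) return(1)
  unname(r["TP"] / denom)
}

#' @rdname iou
#' @export
mean_iou <- function(counts) {
  mean(vapply(seq_len(nrow(counts)) - 1L, function(cl) iou(counts, cl), 1))
}

#' Precision and recall from confusion counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`. A zero denominator scores 1
#' when the class is absent from both masks (nothing to find, nothing
#' claimed), otherwise 0.
#'
#' @inheritParams iou
#' @return Named vector `c(precision, recall)`.
#' @export
precision_recall <- function(counts, class_id) {
  r <- counts[class_id + 1L, ]
  absent <- (r["TP"] + r["FP"] + r["FN"]) == 0
  p <- if (r["TP"] + r["FP"] > 0) r["TP"] / (r["TP"] + r["FP"]) else as.numeric(absent)
  rc <- if (r["TP"] + r["FN"] > 0) r["TP"] / (r["TP"] + r["FN"]) else as.numeric(absent)
  c(precision = unname(p), recall = unname(rc))
}

# boundary pixels: mask minus its 1-px (8-neighbourhood) erosion;
# image-border foreground pixels count as boundary
boundary_pixels <- function(mask) {
  mask <- mask != 0
  if (!any(mask)) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(0, h + 2L, w + 2L)   # image border counts as background
  padded[2:(h + 1L), 2:(w + 1L)] <- mask
  er <- EBImage::erode(padded, EBImage::makeBrush(3, "box"))[2:(h + 1L), 2:(w + 1L)] > 0.5
  mask & !er
}

# Euclidean distance from every pixel to the nearest TRUE pixel of `set`
distance_to_set <- function(set) {
  if (!any(set)) return(matrix(Inf, nrow(set), ncol(set)))
  EBImage::distmap(1 - set, metric = "euclidean")
}

#' Boundary F1 score
#'
#' Boundary pixels are the mask minus its one-pixel erosion. Boundary
#' precision is the fraction of predicted boundary pixels within
#' `tolerance_px` (Euclidean) of a true boundary pixel; boundary recall is
#' symmetric; BF is their harmonic mean (0 when P + R = 0, 1 when both
#' boundaries are empty). `mean_bf()` averages the per-class BF over all
#' classes.
#'
#' @param pred,truth binary masks of equal size.
#' @param tolerance_px matching tolerance in pixels (default 2).
#' @return BF score in `[0, 1]`.
#' @export
boundary_f1 <- function(pred, truth, tolerance_px = 2) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  pb <- boundary_pixels(pred)
  tb <- boundary_pixels(truth)
  if (!any(pb) && !any(tb)) return(1)
  if (!any(pb) || !any(tb)) return(0)
  p <- mean(distance_to_set(tb)[pb] <= tolerance_px)
  r <- mean(distance_to_set(pb)[tb] <= tolerance_px)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' @rdname boundary_f1
#' @param n_classes number of classes.
#' @export
mean_bf <- function(pred, truth, n_classes = 3L, tolerance_px = 2) {
  p <- if (inherits(pred, "label_mask")) pred$labels else pred
  g <- if (inherits(truth, "label_mask")) truth$labels else truth
  mean(vapply(seq_len(n_classes) - 1L,
              function(cl) boundary_f1(p == cl, g == cl, tolerance_px), 1))
}

#' Root-mean-square error of a probability map against a binary mask
#'
#' @param pred_prob H x W map of class probabilities in `[0, 1]` (or hard
#'   labels when `hard = TRUE`).
#' @param truth binary mask.
#' @param hard threshold `pred_prob` at 0.5 before scoring.
#' @return Non-negative RMSE.
#' @export
rmse <- function(pred_prob, truth, hard = FALSE) {
  if (!identical(dim(pred_prob), dim(truth))) stop("shape mismatch")
  if (min(pred_prob) < 0 || max(pred_prob) > 1)
    stop("probabilities must lie in [0, 1]")
  p <- if (hard) (pred_prob >= 0.5) + 0 else pred_prob
  sqrt(mean((p - (truth != 0))^2))
}

#' Overall pixel accuracy
#'
#' @param pred,truth [label_mask]s or integer matrices of equal size.
#' @return Fraction of pixels whose predicted class equals the reference.
#' @export
pixel_accuracy <- function(pred, truth) {
  p <- if (inherits(pred, "label_mask")) pred$labels else pred
  g <- if (inherits(truth, "label_mask")) truth$labels else truth
  if (!identical(dim(p), dim(g))) stop("shape mismatch")
  mean(p == g)
}

#' Full per-image metrics report
#'
#' Assembles every evaluation quantity for one predicted/reference mask
#' pair: overall pixel accuracy, per-class and mean Dice, per-class and mean
#' IoU, per-class and mean boundary F1, per-class precision and recall, and
#' (when a probability map is supplied) RMSE per class.
#'
#' @param pred,truth [label_mask]s of equal size.
#' @param probs optional H x W x C class-probability array for RMSE.
#' @param n_classes number of classes.
#' @param tolerance_px boundary-F1 tolerance.
#' @return Object of class `metrics_report` (a list of the quantities).
#' @export
metrics_report <- function(pred, truth, probs = NULL, n_classes = 3L,
                           tolerance_px = 2) {
  p <- if (inherits(pred, "label_mask")) pred$labels else pred
  g <- if (inherits(truth, "label_mask")) truth$labels else truth
  cts <- confusion(p, g, n_classes)
  cls <- seq_len(n_classes) - 1L
  dice_pc <- vapply(cls, function(cl) dice(p == cl, g == cl), 1)
  iou_pc <- vapply(cls, function(cl) iou(cts, cl), 1)
  bf_pc <- vapply(cls, function(cl) boundary_f1(p == cl, g == cl, tolerance_px), 1)
  pr <- t(vapply(cls, function(cl) precision_recall(cts, cl), numeric(2)))
  rmse_pc <- if (!is.null(probs))
    vapply(cls, function(cl) rmse(probs[, , cl + 1L], g == cl), 1) else NULL
  structure(list(accuracy = pixel_accuracy(p, g),
                 dice_per_class = dice_pc, dice_mean = mean(dice_pc),
                 iou_per_class = iou_pc, mean_iou = mean(iou_pc),
                 bf_per_class = bf_pc, mean_bf = mean(bf_pc),
                 precision = pr[, 1], recall = pr[, 2],
                 rmse_per_class = rmse_pc,
                 confusion = cts, n_classes = n_classes),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.4f | mean Dice %.4f | mean IoU %.4f | mean BF %.4f\n",
              x$accuracy, x$dice_mean, x$mean_iou, x$mean_bf))
  tab <- rbind(dice = x$dice_per_class, iou = x$iou_per_class,
               bf = x$bf_per_class, precision = x$precision, recall = x$recall)
  colnames(tab) <- paste0("class", seq_len(x$n_classes) - 1L)
  print(round(tab, 4))
  invisible(x)
}
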