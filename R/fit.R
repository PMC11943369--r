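#' Training control parameters
#'
#' Defaults follow the reference training protocol: 128 x 128 patches,
#' batch size 10, a constant Adam learning rate of 0.001 and up to 300
#' optimization steps. `min_epochs`/`patience` govern early stopping on
#' validation Dice.
#'
#' @param patch_size length-2 training patch size; clipped to the image
#'   size when images are smaller.
#' @param batch_size patches per optimization step.
#' @param learning_rate Adam learning rate (constant; no schedule).
#' @param max_epochs,max_steps training stops at whichever comes first.
#' @param steps_per_epoch optimization steps per logged epoch; the default
#'   `NULL` uses `ceiling(max_steps / max_epochs)` (6 under the defaults,
#'   the ratio of the reference protocol's 300 iterations to its 50
#'   epochs).
#' @param min_epochs epochs to run before early stopping may trigger.
#' @param patience epochs without validation-Dice improvement that trigger
#'   early stopping.
#' @param w_dice,w_ce loss weights (Dice part, cross-entropy part).
#' @param seed integer seed controlling initialization and sampling.
#' @return A `weedseg_control` list.
#' @export
weedseg_control <- function(patch_size = c(128L, 128L), batch_size = 10L,
                            learning_rate = 0.001, max_epochs = 50L,
                            max_steps = 300L, min_epochs = 20L,
                            patience = 10L, w_dice = 1, w_ce = 1, seed = 0L,
                            steps_per_epoch = NULL) {
  structure(list(patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 max_steps = as.integer(max_steps),
                 steps_per_epoch = if (is.null(steps_per_epoch)) NULL
                                   else as.integer(steps_per_epoch),
                 min_epochs = as.integer(min_epochs),
                 patience = as.integer(patience),
                 w_dice = w_dice, w_ce = w_ce, seed = as.integer(seed)),
            class = "weedseg_control")
}

# per-band min-max intensity normalization of a cube
normalize_bands <- function(pixels) {
  for (b in seq_len(dim(pixels)[3])) {
    rng <- range(pixels[, , b])
    pixels[, , b] <- if (diff(rng) < 1e-12) 0
                     else (pixels[, , b] - rng[1]) / diff(rng)
  }
  pixels
}

# method-specific single-channel-stack input for the segmentation network
# (fusion inputs are produced by the fusion network at run time instead)
method_input <- function(method, scene) {
  switch(method,
         pca = pca_reduce(scene$vis, scene$nir)$pixels,
         nir_norm = normalize_bands(scene$nir$pixels),
         stop("no precomputed input for method ", method))
}

#' Fit a plant/weed segmentation model
#'
#' The main fitting entry point. `method = "fusion"` trains the two-stage
#' pipeline — dual-branch fusion network with channel attention feeding a
#' zero-padded U-Net — end to end with a combined soft-Dice +
#' cross-entropy loss. `method = "pca"` trains the U-Net on a per-image
#' 3-band PCA reduction of the stacked VIS/NIR cube, and
#' `method = "nir_norm"` on the per-band min-max-normalized NIR cube.
#' Training samples random patches from the training scenes, evaluates
#' validation Dice each epoch, checkpoints the best model and stops early
#' when validation Dice plateaus.
#'
#' @param data list with `scenes` (each a list with `vis`, `nir`,
#'   `labels`) and `split` (character tags), e.g. from [make_benchmark()].
#' @param method `"fusion"`, `"pca"` or `"nir_norm"`.
#' @param control a [weedseg_control()] list.
#' @param fusion a [fusion_config()] (fusion method only).
#' @param unet a [unet_config()]; its `in_channels` is forced to match the
#'   method (8 for fusion/nir_norm, 3 for pca).
#' @param verbose print one history line per epoch.
#' @return An object of class `weedseg` with `print`, `summary`, `coef`,
#'   `plot` and `predict` methods. `$history` holds one row per epoch:
#'   epoch, elapsed seconds, mini-batch accuracy and loss (of the batch
#'   current at logging time), their epoch averages, learning rate,
#'   validation Dice.
#' @export
weedseg <- function(data, method = c("fusion", "pca", "nir_norm"),
                    control = weedseg_control(),
                    fusion = fusion_config(),
                    unet = unet_config(),
                    verbose = FALSE) {
  method <- match.arg(method)
  scenes <- data$scenes
  split <- data$split
  stopifnot(length(scenes) == length(split))
  tr <- which(split == "train")
  va <- which(split == "val")
  if (!length(tr)) stop("empty train split")
  unet$in_channels <- if (method == "pca") 3L else 8L
  n_classes <- unet$n_classes

  inputs <- NULL
  if (method != "fusion")
    inputs <- lapply(scenes, function(s) method_input(method, s))

  dims <- dim(scenes[[tr[1]]]$vis$pixels)
  ph <- min(control$patch_size[1], dims[1])
  pw <- min(control$patch_size[2], dims[2])
  if (ph %% 2L^unet$depth || pw %% 2L^unet$depth)
    stop("patch size must be divisible by 2^depth")
  if (ph > dims[1] || pw > dims[2]) stop("patch larger than images")

  steps_per_epoch <- if (!is.null(control$steps_per_epoch))
    control$steps_per_epoch
  else max(1L, ceiling(control$max_steps / control$max_epochs))
  t0 <- proc.time()[["elapsed"]]

  fit <- with_local_seed(control$seed, {
    pif <- if (method == "fusion") pifnet_init(fusion) else NULL
    up <- unet_init(unet)
    st_u <- adam_init(up)
    st_p <- if (!is.null(pif)) adam_init(pif) else NULL
    history <- NULL
    best <- list(dice = -Inf, epoch = 0L, pif = pif, unet = up)
    gstep <- 0L
    for (epoch in seq_len(control$max_epochs)) {
      ep_loss <- ep_acc <- 0
      for (step in seq_len(steps_per_epoch)) {
        gu <- gp <- NULL
        b_loss <- b_acc <- 0
        for (s in seq_len(control$batch_size)) {
          idx <- tr[sample.int(length(tr), 1L)]
          sc <- scenes[[idx]]
          r0 <- sample.int(dims[1] - ph + 1L, 1L) - 1L
          c0 <- sample.int(dims[2] - pw + 1L, 1L) - 1L
          rows <- r0 + seq_len(ph); cols <- c0 + seq_len(pw)
          lab <- sc$labels$labels[rows, cols]
          if (method == "fusion") {
            pf <- pifnet_forward(sc$vis$pixels[rows, cols, , drop = FALSE],
                                 sc$nir$pixels[rows, cols, , drop = FALSE], pif)
            x <- pf$fused
          } else x <- inputs[[idx]][rows, cols, , drop = FALSE]
          uf <- unet_forward(x, up, unet)
          lg <- loss_and_grad(uf$logits, lab, n_classes,
                              control$w_dice, control$w_ce)
          ub <- unet_backward(lg$dlogits, uf$cache, up, unet)
          gu <- accumulate_grads(gu, ub$grads)
          if (method == "fusion") {
            pb <- pifnet_backward(ub$dx, pf$cache, pif)
            gp <- accumulate_grads(gp, pb$grads)
          }
          b_loss <- b_loss + lg$loss
          b_acc <- b_acc + lg$accuracy
        }
        upd <- adam_step(up, scale_grads(gu, 1 / control$batch_size), st_u,
                         control$learning_rate)
        up <- upd$params; st_u <- upd$state
        if (method == "fusion") {
          updp <- adam_step(pif, scale_grads(gp, 1 / control$batch_size), st_p,
                            control$learning_rate)
          pif <- updp$params; st_p <- updp$state
        }
        ep_loss <- ep_loss + b_loss / control$batch_size
        ep_acc <- ep_acc + b_acc / control$batch_size
        last_loss <- b_loss / control$batch_size
        last_acc <- b_acc / control$batch_size
        gstep <- gstep + 1L
        if (gstep >= control$max_steps) break
      }
      nsteps <- min(step, steps_per_epoch)
      model_now <- structure(list(method = method, pif = pif, unet = up,
                                  fusion_config = fusion, unet_config = unet),
                             class = "weedseg")
      val_dice <- NA_real_
      if (length(va)) {
        vd <- vapply(va, function(i) {
          pm <- predict_scene(model_now, scenes[[i]])
          truth <- scenes[[i]]$labels$labels
          mean(vapply(seq_len(n_classes - 1L),
                      function(cl) dice(pm$labels == cl, truth == cl), 1))
        }, 1)
        val_dice <- mean(vd)
        if (val_dice > best$dice) {
          best <- list(dice = val_dice, epoch = epoch, pif = pif, unet = up)
        }
      }
      # "mini-batch" columns mirror per-epoch training logs: the accuracy
      # and loss of the batch current at logging time
      history <- rbind(history, data.frame(
        epoch = epoch,
        elapsed = proc.time()[["elapsed"]] - t0,
        minibatch_accuracy = last_acc,
        minibatch_loss = last_loss,
        epoch_accuracy = ep_acc / nsteps,
        epoch_loss = ep_loss / nsteps,
        learning_rate = control$learning_rate,
        val_dice = val_dice))
      if (verbose)
        message(sprintf("epoch %3d | %6.1fs | acc %.4f | loss %.4f | lr %g | val Dice %s",
                        epoch, history$elapsed[epoch],
                        ep_acc / nsteps, ep_loss / nsteps,
                        control$learning_rate,
                        ifelse(is.na(val_dice), "-", sprintf("%.4f", val_dice))))
      if (gstep >= control$max_steps) break
      if (length(va) && epoch >= control$min_epochs &&
          epoch - best$epoch >= control$patience) break
    }
    if (length(va) && best$epoch > 0L) { pif <- best$pif; up <- best$unet }
    list(pif = pif, unet = up, history = history, best = best)
  })

  structure(list(method = method,
                 pif = fit$pif, unet = fit$unet,
                 fusion_config = fusion, unet_config = unet,
                 control = control,
                 history = fit$history,
                 best_epoch = fit$best$epoch,
                 best_val_dice = fit$best$dice,
                 class_names = c("soil", "plant", "weed")[seq_len(min(3L, n_classes))]),
            class = "weedseg")
}

# forward one full scene through the fitted pipeline -> label_mask + probs
predict_scene <- function(object, scene) {
  x <- switch(object$method,
              fusion = pifnet_forward(scene$vis$pixels, scene$nir$pixels,
                                      object$pif)$fused,
              pca = pca_reduce(scene$vis, scene$nir)$pixels,
              nir_norm = normalize_bands(scene$nir$pixels))
  probs <- softmax3(unet_forward(x, object$unet, object$unet_config)$logits)
  d <- dim(probs)
  pred <- max.col(mat_view(probs), ties.method = "first") - 1L
  list(labels = matrix(pred, d[1], d[2]), probs = probs)
}

#' Predict a segmentation mask for a scene
#'
#' @param object a fitted [weedseg] model.
#' @param vis,nir co-registered 8-band [multispectral_image]s; sizes must
#'   divide `2^depth` of the network.
#' @param type `"mask"` for a [label_mask], `"prob"` for the H x W x C
#'   probability array.
#' @param ... unused.
#' @export
predict.weedseg <- function(object, vis, nir, type = c("mask", "prob"), ...) {
  type <- match.arg(type)
  out <- predict_scene(object, list(vis = vis, nir = nir))
  if (type == "prob") out$probs
  else label_mask(out$labels, object$class_names)
}

#' @export
print.weedseg <- function(x, ...) {
  cat(sprintf("<weedseg> method: %s | trained %d epoch(s)\n",
              x$method, if (is.null(x$history)) 0L else nrow(x$history)))
  if (!is.null(x$best_epoch) && x$best_epoch > 0L)
    cat(sprintf("  best validation Dice %.4f at epoch %d\n",
                x$best_val_dice, x$best_epoch))
  if (x$method == "fusion")
    cat(sprintf("  fusion: %d branch channels, attention reduction %d\n",
                x$fusion_config$branch_channels,
                x$fusion_config$attention_reduction))
  cat(sprintf("  U-Net: depth %d, base filters %d, %d -> %d channels\n",
              x$unet_config$depth, x$unet_config$base_filters,
              x$unet_config$in_channels, x$unet_config$n_classes))
  invisible(x)
}

#' @export
summary.weedseg <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("\nTraining history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' @export
coef.weedseg <- function(object, ...) {
  list(fusion = object$pif, unet = object$unet)
}

#' @export
plot.weedseg <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(h$epoch, h$minibatch_loss, type = "l", xlab = "epoch",
                 ylab = "mini-batch loss", main = "training loss", ...)
  graphics::plot(h$epoch, h$minibatch_accuracy, type = "l", xlab = "epoch",
                 ylab = "mini-batch accuracy", ylim = c(0, 1),
                 main = "training accuracy", ...)
  if (!all(is.na(h$val_dice)))
    graphics::lines(h$epoch, h$val_dice, lty = 2)
  invisible(x)
}

#' Evaluate a fitted model on a set of scenes
#'
#' Produces per-scene metric reports and the aggregate: pooled pixel
#' accuracy over all pixels, and the mean and population standard deviation
#' of the per-scene foreground Dice scores.
#'
#' @param object a fitted [weedseg] model.
#' @param scenes list of scenes (`vis`, `nir`, `labels`).
#' @return List with `per_scene` ([metrics_report] list), `pixel_accuracy`
#'   (pooled), `dice_mean`, `dice_sd`, `mean_iou`, `mean_bf`, `rmse_mean`.
#' @export
evaluate_scenes <- function(object, scenes) {
  if (!length(scenes)) stop("no scenes to evaluate")
  n_classes <- object$unet_config$n_classes
  correct <- total <- 0
  reports <- vector("list", length(scenes))
  dices <- numeric(length(scenes))
  for (i in seq_along(scenes)) {
    pr <- predict_scene(object, scenes[[i]])
    truth <- scenes[[i]]$labels$labels
    reports[[i]] <- metrics_report(pr$labels, truth, probs = pr$probs,
                                   n_classes = n_classes)
    correct <- correct + sum(pr$labels == truth)
    total <- total + length(truth)
    dices[i] <- mean(reports[[i]]$dice_per_class[-1L])
  }
  ds <- dice_statistics(dices)
  list(per_scene = reports,
       pixel_accuracy = correct / total,
       dice_mean = unname(ds["mean"]), dice_sd = unname(ds["sd"]),
       mean_iou = mean(vapply(reports, `[[`, 1, "mean_iou")),
       mean_bf = mean(vapply(reports, `[[`, 1, "mean_bf")),
       rmse_mean = mean(vapply(reports, function(r)
         mean(r$rmse_per_class), 1)))
}

#' Instance post-processing of a semantic mask
#'
#' Splits a predicted semantic mask into instances by per-class connected
#' components (idempotent; delegates to [extract_instances()]).
#'
#' @param semantic a [label_mask].
#' @param min_area minimum instance area in pixels.
#' @return An [instance_mask].
#' @export
instance_postprocess <- function(semantic, min_area = 25L) {
  extract_instances(semantic, min_area = min_area)
}
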