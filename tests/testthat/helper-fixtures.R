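# Shared in-code fixtures. Everything is generated; nothing is read from disk.

random_cube <- function(h = 16, w = 16, b = 8, seed = NULL,
                        domain = "VIS") {
  if (!is.null(seed)) set.seed(seed)
  multispectral_image(array(runif(h * w * b), c(h, w, b)),
                      default_band_centers(domain), domain)
}

random_mask_pair <- function(h = 16, w = 16, n_classes = 3) {
  list(pred = matrix(sample(0:(n_classes - 1), h * w, TRUE), h, w),
       truth = matrix(sample(0:(n_classes - 1), h * w, TRUE), h, w))
}

tiny_benchmark <- function(n_train = 3, n_val = 1, n_test = 1, seed = 11) {
  make_benchmark(n_train = n_train, n_val = n_val, n_test = n_test,
                 height = 32, width = 32, seed = seed,
                 n_plants = 2, n_weeds = 1, blob_radius_range = c(4, 8))
}

small_fusion_model <- function(seed = 1) {
  set.seed(seed)
  structure(list(method = "fusion",
                 pif = weedseg:::pifnet_init(fusion_config(branch_channels = 4)),
                 unet = weedseg:::unet_init(unet_config(in_channels = 8,
                                                        depth = 2,
                                                        base_filters = 4)),
                 fusion_config = fusion_config(branch_channels = 4),
                 unet_config = unet_config(in_channels = 8, depth = 2,
                                           base_filters = 4),
                 class_names = c("soil", "plant", "weed")),
            class = "weedseg")
}

# brute-force one-vs-rest confusion tally by explicit pixel loop (oracle)
confusion_oracle <- function(pred, truth, n_classes) {
  out <- matrix(0L, n_classes, 4,
                dimnames = list(NULL, c("TP", "FP", "FN", "TN")))
  for (cl in 0:(n_classes - 1)) for (i in seq_along(pred)) {
    p <- pred[i] == cl; g <- truth[i] == cl
    j <- cl + 1L
    if (p && g) out[j, "TP"] <- out[j, "TP"] + 1L
    else if (p) out[j, "FP"] <- out[j, "FP"] + 1L
    else if (g) out[j, "FN"] <- out[j, "FN"] + 1L
    else out[j, "TN"] <- out[j, "TN"] + 1L
  }
  out
}
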