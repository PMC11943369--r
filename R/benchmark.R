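#' Desk-scale synthetic benchmark: generate, train, evaluate
#'
#' One call reproduces the package's reference experiment on a single CPU:
#' generate the default synthetic benchmark (40 train / 8 val / 8 test
#' scenes of 64 x 64 pixels, sensor noise sd 0.02), train the requested
#' method with 64 x 64 patches, batch size 10 and learning rate 0.001 for
#' up to `max_epochs` epochs with early stopping on validation Dice, and
#' evaluate on the held-out test split.
#'
#' The benchmark uses a compact network (8 branch channels, U-Net depth 2
#' with 8 base filters) so a full run takes minutes on one CPU; all widths
#' remain configurable through `...` for larger experiments.
#'
#' @param method `"fusion"`, `"pca"` or `"nir_norm"`.
#' @param seed master seed; scene generation and training derive their
#'   seeds from it.
#' @param max_epochs training epoch cap.
#' @param min_epochs epochs before early stopping may trigger.
#' @param bench optional pre-generated benchmark (from [make_benchmark()])
#'   to reuse across methods.
#' @param branch_channels,base_filters,depth network widths.
#' @param verbose print per-epoch history lines.
#' @param ... forwarded to [make_benchmark()].
#' @return List with `model` (the fitted [weedseg] object), `evaluation`
#'   (from [evaluate_scenes()] on the test split) and `bench`.
#' @export
run_benchmark <- function(method = c("fusion", "pca", "nir_norm"),
                          seed = 0L, max_epochs = 50L, min_epochs = 20L,
                          bench = NULL, branch_channels = 8L,
                          base_filters = 8L, depth = 2L,
                          verbose = FALSE, ...) {
  method <- match.arg(method)
  if (is.null(bench)) bench <- make_benchmark(seed = seed, ...)
  model <- weedseg(
    bench, method = method,
    control = weedseg_control(patch_size = c(64L, 64L), batch_size = 10L,
                              learning_rate = 0.001, max_epochs = max_epochs,
                              max_steps = 300L, min_epochs = min_epochs,
                              patience = 10L, seed = seed + 1L,
                              steps_per_epoch = 6L),
    fusion = fusion_config(branch_channels = branch_channels),
    unet = unet_config(depth = depth, base_filters = base_filters),
    verbose = verbose)
  test_scenes <- bench$scenes[bench$split == "test"]
  list(model = model,
       evaluation = evaluate_scenes(model, test_scenes),
       bench = bench)
}
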