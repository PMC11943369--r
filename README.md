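# weedseg

Two-stage semantic segmentation of crop plants and weeds in broadband
multispectral imagery, for researchers in precision agriculture and
biological image analysis who work with paired visible (VIS) and
near-infrared (NIR) camera rigs.

RGB images struggle to separate plants from weeds — both are green. The
discriminative signal sits in the near-infrared (the red-edge jump in
vegetation reflectance tracks chlorophyll content) and in fine chroma
differences. `weedseg` implements a pipeline that exploits both:

1. **Fusion stage (PIF-Net).** Two convolutional branches with identical
   structure but independent weights extract features from the 8-band VIS
   cube and the 8-band NIR cube (three 3×3 convolutions + PReLU each). The
   feature maps are concatenated and gated by channel attention — a
   squeeze-and-excitation bottleneck produces a weight *w*<sub>c</sub> ∈ (0,1)
   per channel — and three further 3×3 convolutions reconstruct a fused
   8-band image.
2. **Segmentation stage.** A U-Net with zero-padded convolutions (output
   size = input size) classifies every pixel of the fused image into
   soil / plant / weed, trained with a combined soft-Dice + cross-entropy
   loss:

   Dice = 2|S∩G| / (|S|+|G|),  Dice loss = 1 − Dice.

Baselines for comparison: U-Net on a per-image 3-band PCA reduction of the
16 stacked channels, and U-Net on the per-band intensity-normalized NIR cube.

Around the models, the package provides everything needed to run the
experiment end to end without proprietary data: snapshot MSFA capture
simulation and per-band bilinear demosaicking; a synthetic generator of
co-registered VIS/NIR soil/plant/weed scenes with ground truth; the
chroma-based annotation chain (sRGB → CIELAB → K-means on the a/b plane →
class mapping → instance extraction); and the full metric suite (pixel
accuracy, per-class/mean Dice with population spread, IoU/mean IoU,
boundary F1, precision/recall, RMSE).

## Worked example

```r
library(weedseg)

# a small synthetic benchmark: 12 train / 4 val / 4 test scenes, 64 x 64
bench <- make_benchmark(n_train = 12, n_val = 4, n_test = 4, seed = 1)

fit <- weedseg(bench, method = "fusion",
               control = weedseg_control(patch_size = c(64, 64),
                                         max_epochs = 25, seed = 1),
               fusion = fusion_config(branch_channels = 8),
               unet = unet_config(depth = 2, base_filters = 8))
fit
#> <weedseg> method: fusion | trained 25 epoch(s)
#>   best validation Dice 0.9733 at epoch 24
#>   fusion: 8 branch channels, attention reduction 4
#>   U-Net: depth 2, base filters 8, 8 -> 3 channels

sc <- bench$scenes[[17]]           # a held-out scene
mask <- predict(fit, sc$vis, sc$nir)
metrics_report(mask$labels, sc$labels$labels)
#> <metrics_report> accuracy 0.9875 | mean Dice 0.9730 | mean IoU 0.9480 | mean BF 0.9854
#>           class0 class1 class2
#> dice      0.9951 0.9683 0.9557
#> iou       0.9903 0.9385 0.9151
#> bf        0.9822 0.9968 0.9771
#> precision 0.9915 0.9778 0.9700
#> recall    0.9987 0.9589 0.9417
```

`class0/1/2` are soil/plant/weed: per-class overlap (Dice, IoU), boundary
agreement within 2 px (bf), and the precision/recall balance of each class.
Training longer on the full benchmark (below) pushes pixel accuracy above
98%.

The ground-truth annotation chain works on any VIS cube:

```r
ann <- annotate_scene(sc$vis, k = 3)       # Lab chroma K-means annotation
pixel_accuracy(ann$labels, sc$labels)      # vs the generator's truth
#> [1] 0.9899902
length(binary_masks(ann$instances))        # one binary mask per instance
#> [1] 3
```

A thin command-line front end over the same functions lives in
`inst/cli/weedseg.R` (subcommands `synth`, `demosaic`, `annotate`,
`benchmark`, `evaluate`).

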