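# segtrans

Binary segmentation of grayscale biomedical images — lung fields in 2D
thoracic CT slices being the motivating case — cast as **paired
image-to-image translation with a conditional adversarial network**, plus
everything needed to evaluate the idea honestly: a supervised U-Net
baseline, Otsu and Canny classical baselines, per-pixel metrics with cohort
summaries, and a calibrated synthetic lung-phantom generator so the entire
pipeline is trainable and testable with no external data.

## The method

Instead of predicting a per-pixel class, the segmenter is a *translator*: a
generator `G` maps the input image `x` to a segmentation-style image, and a
patch-based discriminator `D` judges `(x, candidate)` pairs. Training solves

```
G* = arg min_G max_D  Γ_cGAN(G, D) + λ Γ_L1(G)

Γ_cGAN(G, D) = E[log D(x, y)] + E[log(1 − D(x, G(x, z)))]
Γ_L1(G)      = E‖y − G(x, z)‖₁
```

with `y` the ground-truth mask rendered as an image (foreground 1.0), `z`
realized by dropout kept active during training, and `λ = 100` by default.
At test time the generated image is binarized at 0.5 — translate, then
threshold. The generator is a stride-2 encoder–decoder with skip
connections down to a 1×1 bottleneck; the discriminator is a patch critic
emitting a grid of local real-probabilities. Training uses Adam
(learning rate 2e-4, β₁ = 0.5), batch size 1.

Evaluation follows the field's per-pixel conventions: accuracy,
overlap rate (Jaccard index of the foregrounds), and F-measure (harmonic
mean of pixel precision and recall), summarized per cohort as
min/max/mean/sd.

All network machinery (convolutions via a sparse gather operator and BLAS
matrix products, transposed convolutions as their adjoints, instance
normalization, Adam) is implemented in the package and validated against
finite-difference gradients in the test suite.

## Worked example

Train on 67 synthetic phantoms at 64×64 for 20 epochs and score 30 held-out
phantoms (a desk-scale version of a 67-sample training cohort):

```r
library(segtrans)

params <- phantom_params(image_size = 64L)
ds <- generate_dataset(n_train = 67, n_test = 30, params, seed = 101)

model <- train_pix2pix(ds$train,
                       generator_spec(64L, base_channels = 8L),
                       discriminator_spec(base_channels = 8L),
                       train_config(epochs = 20L, seed = 1L))

preds <- lapply(ds$test, function(p) segment(model, p$image))
records <- score_cohort(preds, ds$test)
summarize_metrics(records, "f_measure")
#>      metric   minimum   maximum      mean standard_deviation
#> 1 f_measure 0.9391304 0.9849341 0.9641846         0.01214624
```

Mean test F-measure ≈ 0.96: the translator segments the phantom lung
fields nearly perfectly at this scale. `model$history` holds the per-epoch
`d_loss`, `g_adv`, `g_l1`, `g_total` trajectory (with
`g_total = g_adv + λ·g_l1` exactly). Compare against the baselines on the
same split with `run_compare()`, or study annotation-error robustness
(training labels with one lung half removed) with `run_label_noise()`.

A command-line wrapper over the same functions is installed at
`inst/cli/segtrans.R`:

```sh
Rscript inst/cli/segtrans.R phantom --output-dir data --n-train 67 --n-test 30 --seed 101
Rscript inst/cli/segtrans.R train --dataset-dir data --output-dir run --method pix2pix --epochs 20
Rscript inst/cli/segtrans.R segment --images-dir data/test/images --output-dir run/masks --method pix2pix --checkpoint run/checkpoint.rds
Rscript inst/cli/segtrans.R evaluate --predicted-dir run/masks --reference-dir data/test/masks --output-dir run/eval
```

## Scope

2D single-channel images only; masks are binary. The phantom generator is a
statistical stand-in for patient data (see the methods vignette for what it
does and does not emulate). No DICOM/HU handling: images are assumed
already windowed to `[0, 1]`.
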