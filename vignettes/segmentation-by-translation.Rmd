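---
title: "Segmentation by translation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation by translation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

segtrans treats binary segmentation as paired image-to-image translation.
A generator network $G$ maps a grayscale input $x \in [0,1]^{n \times n}$ to
a segmentation-style image; a discriminator $D$ receives the channel
concatenation of $x$ and a candidate target and emits a grid of local
real-probabilities (a patch critic: each output cell judges only its
receptive field, which pushes $G$ toward locally crisp structure instead of
globally plausible but blurry output). Training alternates between

* the critic ascending the conditional adversarial objective
  $\mathbb{E}[\log D(x,y)] + \mathbb{E}[\log(1 - D(x, G(x,z)))]$,
  implemented as binary cross-entropy toward 1 on real pairs and 0 on
  generated pairs, averaged and (by default) halved so the critic does not
  outpace the generator; and
* the generator descending the non-saturating adversarial loss
  $-\mathbb{E}[\log D(x, G(x,z))]$ plus $\lambda$ times the L1
  reconstruction loss $\mathbb{E}\lVert y - G(x,z)\rVert_1$.

The non-saturating form replaces literal minimization of the second
adversarial term; it leaves the saddle point unchanged and is the standard
trainability fix. The noise input $z$ is realized by dropout kept active
during training (and optionally at inference via `translate(stochastic =
TRUE)`); no explicit noise vector is drawn. The mask is rendered as the
translation target with foreground 1.0 and background 0.0, matching the
package-wide binarization rule "$\ge 0.5$ is foreground", so inference is
simply `binarize(translate(model, x), 0.5)` — what `segment()` does.

Inside the logs, probabilities are clamped to $[\varepsilon, 1-\varepsilon]$
with $\varepsilon = 10^{-7}$: the adversarial objective is unbounded below,
and the clamp is the package's finiteness contract (`cgan_objective` never
returns `NaN` or `±Inf`).

## Architectures

**Generator.** A stride-2 convolutional encoder (kernel 4, padding 1)
halves the plane at every stage down to a 1×1 bottleneck — hence the
power-of-two input-size requirement — with channels doubling from
`base_channels` and capped at 8×. Leaky rectification (slope 0.2) on the
way down, rectification on the way up, instance normalization everywhere
except the first and innermost encoder stages (a 1×1 plane has no spatial
statistics to normalize), dropout (rate 0.5) in the innermost three decoder
stages, skip connections concatenating each encoder stage's output into the
mirror decoder stage, and a tanh output mapped affinely onto $[0,1]$.

**Critic.** `patch_depth` stride-2 stages (default 3), then two stride-1
stages; at 256×256 this is the customary 70×70-receptive-field patch critic
emitting a 30×30 grid.

**Supervised baseline.** A standard U-shaped network: two 3×3 convolutions
plus rectification per stage, 2×2 max pooling down (default depth 4),
stride-2 transposed convolutions up, skip concatenation, 1×1 output
convolution, trained with mean pixelwise binary cross-entropy — no Dice
term, no augmentation, no schedule, deliberately the minimal default
configuration. Its optimizer, epoch, shuffle and seed semantics are
identical to the translator's so comparisons share a budget.

**Initialization.** Translator and critic weights are drawn from
$\mathcal{N}(0, 0.02)$, the customary recipe for networks interleaved with
normalization. The U-Net has no normalization layers, and the same
initialization attenuates activations through its long conv stack; its
convolutions therefore use He initialization
($\mathcal{N}(0, \sqrt{2/\mathrm{fan_in}})$), the standard choice for
norm-free rectified networks.

**Optimizer.** Adam, learning rate $2 \cdot 10^{-4}$, $\beta_1 = 0.5$,
$\beta_2 = 0.999$, batch size 1 (gradient accumulation implements larger
batches). No learning-rate decay: runs are fixed-epoch. Within one step the
generator's gradient is computed against the current critic and the two
updates are applied together; the critic's parameter gradients accumulated
while backpropagating the generator's adversarial term are discarded.

All of this runs on a small in-package engine: convolutions are lowered to
BLAS matrix products through a precomputed sparse gather operator (im2col),
and transposed convolutions are the adjoints of mirror-geometry
convolutions. Every analytic gradient is validated against central finite
differences in the test suite, which is the load-bearing correctness
argument for the whole training stack.

## Evaluation metrics

Per image, from pixel confusion counts: accuracy $(TP+TN)/N$; overlap rate
$|A \wedge B| / |A \vee B|$ (the Jaccard index of the foregrounds);
precision, recall, and their harmonic mean F. Degenerate denominators
follow fixed conventions — identical empty masks score perfect (overlap of
an empty union is 1, precision with no predicted foreground is 1 when there
was nothing to find), a total miss scores 0, and F is 0 when $P + R = 0$.
Cohort summaries report min/max/mean/sd with the population (divide-by-$n$)
standard deviation. These conventions matter only on degenerate inputs; the
oracle tests exercise all of them.

## The phantom generator

Real thoracic CT under a lung window shows dark lung fields inside a
brighter torso on a near-black background. The phantom emulates exactly
that statistical skeleton: an elliptical torso with mild center/axis
jitter; two lung ellipses (left/right) with independent axis jitter and
rotation up to ±8°; optional bright intralung nodules and vessel-like line
segments; Gaussian blur; additive Gaussian noise, clipped to $[0,1]$. The
ground-truth mask is the exact pre-noise lung geometry, and nodules remain
mask foreground (lesions belong to the lung field).

Calibration: the lung ellipse axes are solved from
`lung_area_fraction_target` (default 0.2543, the mean lung coverage of the
real 267-image cohort the method was developed on) *before* mean-one
jitter, so the expected per-image foreground fraction hits the target while
individual draws vary around it. That cohort's published statistics give
only the mean, not the spread; the ±12% axis jitter and the eccentricity
range 1.35–1.85 are the package's own choice of realistic inter-subject
variation. Intensities are abstract window renderings in $[0,1]$, not
Hounsfield units, because the networks only ever see windowed images; noise
is i.i.d. Gaussian, deliberately ignoring CT's correlated noise texture.

What passing phantom experiments do **not** show: robustness to anatomy
that is not two blobs (hila, pleural effusions, lungs touching the torso
boundary), to scanner artifacts, or to the intensity overlap between lung
parenchyma and airways in real slices. The phantoms make every mechanism
exercisable and every number reproducible; they do not certify clinical
performance.

The annotation-error mode mirrors documented expert mistakes: `half_lung`
deletes one lateral half of the foreground (an expert who segmented only
one lung), `residual_background` adds a spurious band along the torso
border (incomplete background removal), `dilate_erode` perturbs the
boundary. Corrupted pairs always carry `clean_mask`, so experiments can
train on wrong labels yet evaluate against truth.

## Classical baselines, and why they score low

Otsu thresholding is applied in its naive global form with dark-class
polarity: lungs are dark, but so is the background around the torso, so the
predicted foreground engulfs the image border and the overlap with the true
lung mask is poor. Canny is scored edge-pixels-as-mask — a thin boundary
set against a filled region. Both protocols are deliberate: they are the
naive non-learning comparators, and boundary filling or masking heuristics
that would rescue them are intentionally not applied. Canny follows the
textbook definitions the tests pin down: Gaussian smoothing, 3×3 Sobel with
reflected boundary, non-maximum suppression over 4 quantized directions
(retain a pixel when its magnitude strictly exceeds the forward neighbor
and is at least the backward neighbor — the asymmetric tie-break that keeps
an ideal two-pixel tie one pixel wide), and double-threshold hysteresis
with 8-connectivity. Otsu ties break toward the smallest threshold; a
constant image returns its own value and an empty mask.

## Numerical and design choices

* **Boundary rule**: `binarize` treats a pixel exactly at the threshold as
  foreground, everywhere.
* **Mask encoding on disk**: PNG {0, 255}; binarized at 128/255 on load, so
  antialiased third-party masks load sanely. Masks resize nearest-neighbor
  (never leaving {0, 1}); images bilinear, with half-pixel-centered
  coordinates so that same-size resizing is the identity.
* **Determinism**: every stochastic operation is a pure function of its
  seed; `generate_dataset` derives independent sub-seeds per pair, training
  derives shuffle order and dropout from `config$seed`, and checkpoints
  round-trip to bit-identical inference. RNG state is restored after every
  seeded operation.
* **Degenerate inputs**: zero-epoch training returns an initialized,
  inference-capable model with empty history; a constant image through Otsu
  or Canny yields an empty mask; empty directories load as empty datasets.

## Experiment scales

The desk-scale experiment suite runs the full mechanism at reduced size:
64×64 phantoms, 67 training / 30 test pairs, 20 epochs, `base_channels = 8`
for both learned models; the sample-size monotonicity study (237 vs 67
training pairs, 3 seeds) runs at 32×32 with 5 epochs. Channel width and
resolution are capacity knobs orthogonal to the mechanisms under test
(objectives, alternation, skip topology, metrics), and at these scales the
entire suite — including four full adversarial/supervised training runs —
completes on one CPU core in well under half an hour. At the default
256×256 / base 64 scale the same code trains the full-size model;
expect hours per run on CPU.

Under those conditions the trained translator reaches mean test F ≈ 0.96 on
held-out phantoms, both learned methods beat both classical baselines by
far more than 0.3 absolute on mean overlap and F, training on 20%
half-lung-corrupted labels still yields mean F ≥ 0.75 against clean truth
(the model averages over inconsistent annotations rather than reproducing
them), and more training data never hurts across seeds. Each of those
statements is computed, not quoted: the corresponding checks live in
`tests/testthat/test-acceptance.R` and the calibration quantity in
`scripts/acceptance.R`.

## Known limitations

* Single-channel 2D images; no 3D volumes, no multi-class masks.
* CPU-only pure-R training: practical for study-scale experiments, slow at
  full 256×256 / base-64 scale.
* The adversarial game is run with fixed hyperparameters; no early
  stopping, no schedules. Long runs can oscillate (the history exposes
  this).
* The phantom's simplicity means absolute real-data figures cannot be
  inferred from phantom scores; only mechanisms and orderings transfer.
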