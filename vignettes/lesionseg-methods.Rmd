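---
title: "Methods: lesion segmentation with separable and multi-dilated convolutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion segmentation with separable and multi-dilated convolutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionseg)
```

## The problem and the model

Dermoscopic lesion segmentation assigns each pixel of an RGB skin photograph
to lesion or background. The pipeline implemented here has four parts:
artifact-removal preprocessing, deterministic geometric augmentation, an
encoder–decoder convolutional network, and pixel-level overlap scoring.

### Network

The encoder has four stages. Stage $i$ (branch width $F_i$, default ladder
16/32/64/128) applies three branches *to the same stage input*:

1. **Regular branch** — $1\times1$ convolution to $F_i$ channels, ReLU,
   then a $3\times3$ stride-1 max-pool;
2. **DSC branch** — depthwise separable convolution: a $3\times3$ depthwise
   filter per channel followed by a $1\times1$ pointwise projection to
   $F_i$, then swish;
3. **MDC branch** — three chained $3\times3$ dilated convolutions at rates
   1, 2, 3, each followed by batch normalization and swish; the second and
   third convolutions read the concatenation of the block input with the
   previous convolution's output.

The branch outputs are concatenated (stage width $3F_i$), $2\times2$
max-pooled and passed through dropout 0.05. A 256-px input therefore
traverses resolutions $256\to128\to64\to32\to16$; the bottleneck repeats the
three-branch pattern at $16\times16$. The decoder mirrors the encoder with
$3\times3$ stride-2 transposed convolutions, concatenates each upsampled map
with the matching encoder stage's **pre-pool** concatenated features
(standard U-Net practice), and applies MDC then DSC blocks. A $1\times1$
convolution and sigmoid produce the probability map; masks are cut at 0.5.

All layers are bias-free, which keeps the realized weight counts identical
to the parameter-accounting formulas: a standard $k\times k$ convolution
($M\to N$ channels) costs $k^2MN$ weights, its separable factorization
$k^2M + MN$ — the fraction $1/N + 1/k^2$, about $8$–$9\times$ fewer for
$k=3$ at large $N$:

```{r}
s <- conv_spec(3, 1024, 1024, 2048, 2048)
standard_conv_params(s)$parameters / separable_conv_params(s)$parameters
```

Swish $f(x) = x\,\sigma(x)$ is smooth, non-monotonic (its derivative is
negative near $x=-2$), bounded below and unbounded above; its closed-form
derivative $f'(x) = f(x) + \sigma(x)\,(1-f(x))$ is both an exported
operation and the rule the backward pass actually uses. Initialization
follows the published split: He-normal ($\mathcal N(0, \sqrt{2/n})$, $n$ =
fan-in) for regular, dilated and transposed convolutions, Glorot/Xavier
uniform ($\pm\sqrt{6/(F_{in}+F_{out})}$) for the separable factors. The
protocol's summary table says "Xavier" for everything; we treat the detailed
per-layer assignment as authoritative and expose
`model_config(init_scheme = "glorot_all")` for the all-Xavier reading.

### Implementation

No R deep-learning framework exists in the supported environment, so the
network is self-contained: im2col-based convolution kernels (forward and
backward) in C++ via RcppArmadillo, a minimal reverse-mode tape in R, and an
Adam optimizer ($\beta_1=0.9$, $\beta_2=0.999$, $\epsilon=10^{-8}$). The
naive nested-loop convolution references in `conv_math` are deliberately
independent of these kernels and act as oracles in the tests; every backward
pass is additionally validated against central finite differences through
the whole network loss (relative error $\sim10^{-7}$).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `input_size` | 256 | px | must be divisible by $2^4$; the published input size |
| `filter_ladder` | 16/32/64/128 | channels | published per-stage widths |
| `dilation_rates` | 1, 2, 3 | – | MDC receptive-field ladder (extents 3, 5, 7) |
| `dropout_rate` | 0.05 | – | published; after every encoder max-pool only |
| `bottleneck_filters` | 2·max(ladder) | channels | see open questions below |
| `learning_rate` | 0.001 | – | published Adam rate |
| `epochs` | 150 | – | published; desk-scale runs use far fewer |
| `batch_size` | 8 | images | not stated by the protocol; a common CPU-friendly choice |
| `loss` | bce | – | not stated; Dice and bce+dice available |
| `threshold` | 0.5 | probability | not stated; the conventional cut |
| `closing_radius` | 2 | px | disk radius sized for 1–2 px hairs at 256 px |
| `sharpen_amount`, `sharpen_sigma` | 1, 1 | – / px | standard unsharp-mask defaults |
| `gaussian_sigma` | 0 (off) | px | smoothing is praised but not part of the stated closing→sharpening order |

## Preprocessing

Grayscale morphological closing (dilation then erosion, flat disk) fills
dark structures narrower than the disk — hair strokes — while leaving the
much larger lesion intact; it is extensive and idempotent, both asserted in
tests. Sharpening is unsharp masking with clipping to $[0,1]$. The disk
shape, the unsharp-mask form and per-channel (grayscale, not binary)
morphology are this package's choices; the source recipe names the
operations but not their parameters.

## Augmentation

The transform table lists 3 rotations, 12 side-crops, a left-right flip and
a (25, 25) px shift — 17 variants — while the text states 15 samples per
image. The default registry is rotations + crops (= 15) with flip and shift
behind `include_flip` / `include_shift`. Crop amounts "45°, 60°, 90°" are
read as **pixels** (degrees are meaningless for crops). Cropped pairs are
resized back to the frame (bilinear image, nearest-neighbour mask, so masks
stay binary); the mask always receives exactly the geometric transform of
its image, asserted bit-exactly for the lossless transforms.

## Metrics

Confusion counts treat lesion pixels as positives. Dice
$2TP/(2TP+FP+FN)$, Jaccard $TP/(TP+FP+FN)$, accuracy, sensitivity
$TP/(TP+FN)$ — and specificity implemented **verbatim from the printed
protocol as $TP/(TP+FP)$**, which is algebraically the precision. Reports
carry the textbook $TN/(TN+FP)$ alongside as `corrected_specificity` and
label which is which. Averaging modes: `none` (mean of per-image foreground
scores), `micro` (counts pooled before scoring), `macro` (pooled counts
scored with foreground and background each taken as positive, averaged).
Degenerate all-background comparisons define Dice/Jaccard of two empty masks
as 1 (configurable via `empty_value`).

## Synthetic scenes: what a green test establishes

`make_scene()` renders an elliptical lesion whose radius is modulated by
smooth harmonic noise $r(\theta) = r_0\,(1 + \sum_{k\le8} a_k \sin(k\theta +
\phi_k))$ — emulating the uneven borders of melanoma — darker (mean ~0.3)
than the skin background (~0.75), with Gaussian colour texture, a linear
illumination ramp, and optional dark hair strokes and bright bubbles that
corrupt the image but never the mask. Defaults: area fraction uniform on
(0.05, 0.4), irregularity 0.15, 3 hairs of width 2 px, illumination 0.1,
noise sd 0.03 — plausible magnitudes for dermoscopy chosen once, not tuned.

The generator provides exact ground truth and the contrast structure of
dermoscopy, so it can establish that the implementation *learns* — that
gradients flow, the optimizer descends, and a trained model generalizes to
held-out scenes (Dice ≥ 0.90 at 64 px in the acceptance suite). It does
**not** establish clinical performance: real lesions have weaker and more
variable contrast, textured interiors, vignetting, rulers and colour charts;
the published real-data scores (Dice 0.97 DermIS/DermQuest, 0.947 ISBI2016)
require those datasets and 150-epoch training and are out of scope here.
Real data arranged as `images/` + `masks/` folders can be dropped in
unchanged.

## Numerical choices

- "Same" zero padding, stride 1, cross-correlation (no kernel flip)
  everywhere inside blocks; 0-based (row, column) indexing in the kernels.
- Batch norm: $\epsilon = 10^{-3}$, running-stat momentum 0.9; batch
  statistics in training, running statistics at inference.
- BCE is computed from logits in the stable softplus form; the soft-Dice
  loss uses smoothing constant 1.
- Ties in max-pooling resolve to the first maximum in column-major order.
- Determinism: all randomness (weights, data order, dropout, scenes) flows
  from R's RNG, so a fixed seed reproduces datasets bit-exactly and training
  losses exactly on a given BLAS.

## Open questions resolved here

- **Bottleneck "16 × 16 × 2323"**: the channel figure is treated as a typo;
  only the 16×16 spatial size is contractual. Branch width continues the
  ladder as $2\cdot\max(\text{ladder})$, giving 768 concatenated channels.
- **MDC "dilated filters of size 1×1, 2×2, 3×3"**: read as three 3×3
  kernels at **rates** 1/2/3 (even-sized dilated kernels are anomalous and
  the block is named *multi-dilated*); `mdc_mode = "sizes"` gives the
  literal kernel-size reading.
- **Branch wiring**: the three encoder branches all read the stage input,
  and the $n$-th MDC convolution reads block input ⊕ previous output — one
  consistent reconstruction of the prose description of the block figure.
- **DSC internal order**: depthwise then pointwise (the figure's order; the
  text's "1 × 1 and 3 × 3" listing order is noted as discrepant).
- **Loss, batch size, validation protocol**: never stated; defaults BCE,
  8, and a seeded 80/20-style split left to the caller.

## Limitations

Single-CPU, double-precision, no GPU path; no learning-rate schedules or
early stopping beyond best-loss checkpointing; no pretrained encoders or
attention modules (explicitly out of scope); hair removal is morphological,
not inpainting-based. The 150-epoch, 256-px published configuration runs but
is slow in pure CPU R — the package's tested envelope is the desk scale used
throughout this vignette.
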