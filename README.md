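# lesionseg

Automatic segmentation of skin lesions in dermoscopic photographs: given an
RGB image of a pigmented lesion, produce the per-pixel binary mask that
delineates the lesion from surrounding skin. Accurate delineation is the
first step of computer-aided melanoma screening, and it is hard precisely
where screening matters — melanoma borders are irregular, contrast with
normal skin can be weak, and dermoscopy images carry artifacts (hairs, air
bubbles, uneven illumination).

The package is aimed at image-analysis researchers who want a compact,
fully-tested, dependency-light reimplementation of a modern encoder–decoder
segmentation recipe in R, exercisable end to end without any external data:
a seeded synthetic dermoscopy scene generator ships with the package.

## What is inside

**Pipeline.** Preprocessing (grayscale morphological closing with a disk
structuring element to suppress hair strokes, then unsharp-mask sharpening;
optional Gaussian smoothing) → 15-fold deterministic geometric augmentation
(rotations 90°/180°/270° and crops of 45/60/90 px from each side, with
left-right flip and a (25, 25) px shift available behind flags) → a
UNet-style network → Dice/Jaccard/accuracy/sensitivity/specificity scoring
with `none` / `micro` / `macro` averaging.

**Network.** A 4-level encoder whose stages run three parallel branches on
the stage input — a 1×1 convolution + 3×3 max-pool (ReLU), a
depthwise-separable convolution (DSC) block, and a multi-dilated convolution
(MDC) block — concatenate them, then 2×2 max-pool with dropout 0.05; a
bottleneck of the same three branches at 16×16 (for 256-px inputs); and a
decoder of 3×3 stride-2 transposed convolutions with skip connections to the
encoder's pre-pool features, closed by a 1×1 convolution + sigmoid. Swish
activations *f(x) = x σ(x)* follow every dilated and separable convolution;
batch normalization follows every dilated convolution. Filter ladder
16/32/64/128 by default.

A depthwise-separable convolution factors a k×k convolution with M inputs
and N outputs into a per-channel k×k depthwise filter plus a 1×1 pointwise
projection, shrinking the weight count from `k²MN` to `k²M + MN` — a ratio
of `1/N + 1/k²`, i.e. about 8–9× fewer parameters for k = 3 at large N. A
dilated (atrous) convolution spaces its taps r pixels apart
(`y[i] = Σ_k x[i + r·k] w[k]`), widening the receptive field at no parameter
cost; the MDC block chains rates 1, 2, 3.

There is no deep-learning framework dependency: convolution forward/backward
kernels are implemented in C++ (RcppArmadillo), differentiated through a
small reverse-mode tape, and optimized with Adam (learning rate 0.001). Naive
nested-loop reference convolutions serve as independent oracles in the test
suite, and every backward pass is checked against finite differences.

## Worked example

Desk-scale stand-in for a real training run: 64 synthetic 64×64 scenes,
filter ladder 8/16/32/64, six epochs of Adam on binary cross-entropy
(~2 min on one CPU).

```r
library(lesionseg)
set.seed(1)
cfg <- model_config(input_size = 64L, filter_ladder = c(8L, 16L, 32L, 64L))
model <- build_model(cfg)
trainset <- make_dataset(64, scene_spec(size = 64), seed = 7)
fit <- train(model, trainset, train_config(epochs = 6L, batch_size = 8L, seed = 1))
print(round(fit$history, 4))
#>   epoch   loss accuracy
#> 1     1 0.6193   0.6140
#> 2     2 0.4074   0.8928
#> 3     3 0.3452   0.9363
#> 4     4 0.3049   0.9490
#> 5     5 0.2659   0.9605
#> 6     6 0.2322   0.9654
heldout <- make_dataset(8, scene_spec(size = 64), seed = 8)
evaluate(fit$model, heldout, mode = "none")
#> mode=none accuracy=0.9672 dice=0.9330 jaccard=0.8752 sensitivity=0.9970 specificity=0.8775 (printed form; corrected=0.9544)
```

The history shows the loss descending and pixel accuracy rising epoch by
epoch; after six epochs the model recovers held-out lesion masks with mean
Dice 0.933 (train a few epochs longer and it passes 0.97 — the package's
acceptance suite requires ≥ 0.90 within 50 epochs). `specificity` is
reported with the evaluation protocol's printed formula TP/(TP+FP) (which is
algebraically the precision); the textbook TN/(TN+FP) is shown alongside as
`corrected` — here 0.9544.

Parameter economy of the separable factorization, as printed by
`lesionseg cost --kernel 3 --in-channels 3 --out-channels 16`:

```r
s <- conv_spec(3, 3, 16, 256, 256)
standard_conv_params(s)   # parameters 432, mult_adds 28311552
separable_conv_params(s)  # parameters 75,  mult_adds  4915200
```

## Command line

`exec/lesionseg` exposes the whole pipeline:

```sh
lesionseg synth --n 16 --size 128 --seed 1 --out data
lesionseg preprocess --in data/images --out data/clean
lesionseg augment --in data --out data_aug --size 128
lesionseg train --config cfg.yaml
lesionseg predict --weights weights.rds --in data/images --out preds
lesionseg evaluate --pred preds --truth data/masks --mode micro
lesionseg summary --config cfg.yaml
lesionseg cost --kernel 3 --in-channels 3 --out-channels 16
```

Datasets use the `images/` + `masks/` folder convention with matching
filename stems and 0/255 PNG masks (the de-facto ISIC ground-truth layout),
so real dermoscopy datasets arranged that way can be used directly in place
of synthetic data.

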