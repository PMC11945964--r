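---
title: "Multi-scale, multi-branch attention fusion for radial EBUS classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale, multi-branch attention fusion for radial EBUS classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5, fig.height = 4)
library(ebusfusion)
```

## The problem

Radial endobronchial ultrasound (EBUS) places a rotating 20 MHz transducer
inside an airway, producing a circular B-mode field centered on the probe.
Whether a peribronchial lesion is benign or malignant is decided by biopsy,
but the sonographic appearance of the lesion — its internal echo texture and
the regularity of its margin — carries diagnostic signal that a CNN can
learn. Two practical obstacles shape the design of this package:

* **Scale matters.** The discriminative cues live at different physical
  scales: margin irregularity needs a wide field of view, internal
  heterogeneity a narrow one. A single crop wastes one or the other.
* **Cohorts are imbalanced at the case level.** Malignant disease generates
  far more imaging encounters; a realistic cohort has on the order of six
  times more malignant than benign *cases*, even when the number of images
  per class is balanced by sampling frames more densely from benign videos.

The package implements a complete pipeline around these two observations:
probe-centered multi-scale cropping, polar unwrapping, multi-scale RGB
composites, per-branch CNN encoders, three attention-based feature-fusion
modules, a case-count-weighted loss, a two-stage training protocol, and
patient-level stratified cross-validation — plus a synthetic phantom
generator so everything is exercisable without clinical data.

## Geometry: crops and polar unwrapping

Calibration (pixels per cm) and the probe-center pixel travel in the cohort
manifest; the package performs no scale-mark detection of its own. Four
probe-centered square crops are defined — 4, 3, 2 and 1 cm of side (Types
1–4) — and `slbic_crop()` returns exact sub-arrays, never resampling. All
pixel coordinates are 0-based `(row, col)` with half-open ranges; an
even-sided crop of side $s$ covers rows $[c - s/2,\; c + s/2)$ around probe
row $c$.

`polar_transform()` resamples a radial image onto (radius, angle) axes.
The convention is stated exactly so results are bit-reproducible: output
pixel $(i, j)$ on an $n_r \times n_a$ grid samples the input at

$$r = \frac{i + 0.5}{n_r}\, r_{\max}, \qquad
  \theta = \frac{j + 0.5}{n_a}\, 2\pi,$$

at image position (row $= c_r - r\sin\theta$, col $= c_c + r\cos\theta$):
rows index radius outward, columns sweep a full turn counter-clockwise from
the +col direction. Nothing is ever sampled outside the image — the
precondition $r_{\max} \le$ (distance from probe center to the nearest
edge) is enforced, and a violation is a loud geometry error rather than a
silent extrapolation. Whether the clinical transform of the original
acquisition pipeline maps radius to rows or columns, or spans a sector
rather than $2\pi$, is not publicly documented; the convention above is
this package's own documented choice, verified against a brute-force
per-pixel oracle in the tests.

Gray-scale conversion uses ITU-R BT.601 luma ($0.299R + 0.587G + 0.114B$,
rounded half-up), the common still-image default. Resizing is bilinear with
half-pixel center alignment and is exactly the identity at the target size.

## Multi-scale composites

`generate_multiscale()` merges the gray-scale versions of three crop types
into one RGB image, giving the encoder simultaneous access to three
physical scales. Six variants exist: MS 1-2-3, MS 1-2-4 and MS 2-3-4 from
the plain crops and PMS 1-2-3, PMS 1-2-4, PMS 2-3-4 from their polar
counterparts. The channel order is fixed by ascending type id (largest
field of view in R); no convention for the channel assignment is documented
for the original acquisition pipeline, and any fixed order is equivalent up
to a permutation the encoder's first convolution absorbs. Channels are
copied bit-exactly, so extracting them recovers the sources.

```{r multiscale}
multiscale_specs()
```

## Encoders

Each branch runs a CNN backbone whose classifier is replaced by a
three-layer head — FC($d \to h_1$) → BatchNorm → ReLU → Dropout →
FC($h_1 \to h_2$) → BatchNorm → ReLU → Dropout → FC($h_2 \to 2$) — with
$(h_1, h_2) = (512, 128)$ and dropout 0.5 by default. The head widths and
the exact placement of BatchNorm/Dropout inside the head are configurable
(`encoder_config()`): the design reading adopted here places a
BatchNorm+Dropout pair after each of the first two FC layers and nothing
after the output layer, since regularizing the logits themselves is never
meaningful.

Twelve ImageNet-pretrained backbone names are accepted by
`encoder_config()` for completeness, but instantiating them requires a
pretrained-vision library this package deliberately does not bundle. All
bundled experiments use `tiny_cnn`, a three-stage stride-2 backbone
(8/16/32 channels, ~90k parameters with its head) whose final 32-channel
map plays the role the larger backbones' last convolutional block plays:
at any input size the three stride-2 stages divide the spatial grid by 8,
and global average pooling makes the head size-independent. It trains on a
single CPU in seconds to minutes, which is what makes the end-to-end test
suite feasible.

Feature extraction for fusion always runs in evaluation mode — dropout
inactive, normalization statistics frozen — so repeated extraction is
bit-identical and never mutates the encoder.

## Fusion modules

Three attention-based designs fuse the per-branch feature maps
$F_1, \dots, F_k$ (2–4 branches; maps on different grids are first
adaptively average-pooled to the smallest grid):

* **FFM-v1** — each branch is gated by CBAM (channel attention via a shared
  two-layer MLP over global-average and global-max descriptors, then
  spatial attention via a $7\times7$ convolution over channel-mean and
  channel-max maps) with an additive residual, $F_k' = F_k +
  \mathrm{CBAM}(F_k)$; the gated maps are channel-concatenated and passed
  through multi-head self-attention (MHSA): $F'' = \mathrm{MHSA}(\mathrm{concat}(F_1',\dots))$.
* **FFM-v2** — the simplest: $X = \mathrm{concat}(F_1,\dots,F_k)$ and
  $F'' = X + \mathrm{MHSA}(X)$.
* **FFM-v3** — the v2 map path in parallel with a vector path that treats
  the per-branch FC-layer features (width $h_2$) as tokens,
  $F_2' = X_v + \mathrm{MHSA}(X_v)$; the pooled map path and the flattened
  vector path are concatenated into a single fused vector, so the
  classifier sees local (map) and global (FC) information together.

MHSA tokenizes a $C \times h \times w$ map as $h\cdot w$ spatial tokens
with embedding width $C$ and no positional encoding; this keeps the
parameter count independent of the grid size and makes the operator exactly
permutation-equivariant, a property the tests check directly. The head
count defaults to the largest of 8, 4, 2, 1 dividing the embedding width,
so any branch combination is valid. Whether v1 should carry a second
residual around its MHSA stage is ambiguous in the original description,
which attaches the residual language to the CBAM stage only; v1 therefore
applies the residual at the CBAM stage alone (an ablation flag removes it),
while v2/v3 place it around the attention as described for them. The two
attention paths of v3 are independent modules that share no parameters.

The classifier is adaptive-average-pool → flatten → BatchNorm → FC for
map-shaped fusion output and BatchNorm → FC for v3's vector. The whole
network core (convolution via im2col/GEMM, batch normalization, dropout,
CBAM, MHSA, Adam) is implemented in vectorized R over BLAS with
hand-derived backward passes; every layer's gradients are verified against
central finite differences in the test suite, which is the load-bearing
correctness argument for everything the training loop produces.

## Loss weighting and the two-stage protocol

With $N_b$ benign and $N_m$ malignant **cases** in the training split, the
loss weights are obtained by normalizing the counts, taking reciprocals,
and renormalizing:

$$w_b = \frac{N_m}{N_b + N_m}, \qquad w_m = \frac{N_b}{N_b + N_m},$$

so the weights are inversely proportional to the case counts and sum to
one. For the cohort structure this package targets (6 benign vs 40
malignant training cases) this gives $w_b = 0.8696$, $w_m = 0.1304$.
Weighted cross-entropy multiplies each sample's negative log-likelihood by
its class weight, with mean reduction; equal weights recover plain
cross-entropy up to the factor 0.5.

Training is two-staged. Stage 1 fine-tunes one full encoder per image type
(Adam, weight decay $5\times10^{-4}$, learning rate $10^{-3}$, batch size
32, up to 200 epochs). Stage 2 freezes every encoder — their parameters
are bit-identical before and after, and the package verifies this — and
trains only the fusion module and classifier on features extracted once in
evaluation mode. Extracting once (rather than re-augmenting and
re-extracting each epoch) is this package's choice: augmentation is a
regularizer for encoder fine-tuning, and with the encoders frozen repeated
extraction would add cost without adding trainable signal. Early stopping
monitors the validation loss with patience 6 and restores the best
checkpoint; monitoring loss (not accuracy or AUC) and restoring (not
keeping the last epoch) are deliberate choices where the protocol is
otherwise open. Stage 2 reuses the stage-1 optimizer settings.

Augmentation draws one transform per frame — horizontal/vertical flips,
a 90° rotation count, and brightness/contrast/saturation jitter (default
±20%, unspecified upstream) — and applies it identically to every branch
image of that frame, keeping the branches' geometry synchronized. Pixel
values are scaled from [0, 255] to [0, 1] before entering the network.

## Evaluation

Seven metrics are reported: accuracy, F1, AUC, PPV, NPV, sensitivity and
specificity, with malignant as the positive class and threshold 0.5 for the
threshold-dependent six (the threshold is this package's choice; AUC, the
primary metric, is threshold-free). A ratio with a zero denominator is
reported as `NA` with a warning, never silently as 0, because silent zeros
corrupt cross-fold means. AUC is the trapezoidal area under the ROC built
from all distinct thresholds, identical to the Mann–Whitney statistic with
ties scored ½ — the tests enforce the identity against an $O(n^2)$
pair-counting oracle.

Splitting is always at case level: no patient contributes images to more
than one of train/validation/test, while metrics are computed per image.
`make_fold_plan()` builds stratified four-fold plans in which each fold's
non-test cases split roughly 2:1 into training and validation per class,
and `cross_validate()` runs the full two-stage protocol per fold, reporting
per-fold metrics and their unweighted mean (mean of folds, not pooled
counts). A fixed train/valid/test split is supported alongside k-fold
cross-validation as a separate mode; the two coexist because study designs
commonly report both.

## The phantom generator

`generate_cohort()` renders synthetic radial-EBUS cases so that every
downstream stage is testable with zero external data. A frame consists of a
piecewise-smooth echo template — mid-echo background (0.45), dark probe
disk (0.06), hypoechoic lesion (0.22) on a normalized scale — under
multiplicative log-normal speckle. The log-noise field is band-limited with
a separable (1,2,1)/4 kernel because B-mode speckle is spatially correlated
at the scale of the resolution cell; the marginal variance is restored
after smoothing so `speckle_scale` keeps its meaning. Benign lesions are
homogeneous disks with circular margins; malignant lesions add smooth
sinusoidal internal texture and a sinusoidally perturbed margin (3 random
harmonics of order 3–7). Frames within a case share geometry and texture
parameters and differ by small pose jitter and fresh speckle, mimicking
consecutive video frames. Everything derives deterministically from one
seed via per-case and per-frame hashed streams, so cohorts regenerate
byte-identically.

Defaults mirror the target cohort structure: 13 benign vs 82 malignant
cases, 12 frames per case, 50 px/cm on 256 px frames (a 4 × 4 cm Type-1
crop always fits), probe radius 0.25 cm, lesion radii 0.8–1.4 cm,
`speckle_scale` 0.3. Two knobs create harder regimes: `class_separation`
scales the malignant appearance cues, and `p_ambiguous` renders a fraction
of cases with the *other* class's appearance while keeping their label —
emulating sonographically ambiguous lesions and producing genuinely
overlapping classes, which is the regime where loss weighting matters.

What the phantom does *not* model is equally important: there is no
point-spread function, no attenuation or shadowing, no burned-in overlays,
and the benign/malignant appearance contrast is a constructed stand-in,
not a claim about real EBUS sonographic features. Passing tests demonstrate
that the pipeline's machinery — geometry, optimization, fusion, protocol —
works end to end on data with a known learnable structure; they say nothing
about clinical performance.

## Study sizes and numerical choices

The bundled experiments are sized for a single CPU. The two-branch
learnability study uses a 60-case cohort (12 benign / 48 malignant,
preserving the target imbalance), 5 frames per case, 64 px branch inputs,
the Type-4 crop and polar-Type-3 branches, FFM-v2, patience 6, three
seeds. The imbalance study uses a 112-case cohort at 6:1 (16/96) with
`p_ambiguous = 0.2`, 48 px inputs and five seeds; it runs with patience 10
(up to 60 epochs) because its validation split is small and noisy — with
the short patience the runs stop before the loss-weight effect on the
decision boundary has settled, and the comparison would measure stopping
noise rather than the loss design. Input sizes below 224 are purely a
cost choice: the tiny backbone is fully convolutional and
size-independent.

Other numerical details: He-style initialization scaled by fan-in;
BatchNorm uses biased batch variance for normalization and unbiased
updates of running statistics (momentum 0.1, eps $10^{-5}$); Adam folds
weight decay into the gradient (the convention of mainstream deep-learning
stacks); softmax rows are max-shifted before exponentiation; ties in
`max`-based CBAM descriptors break toward the first index for determinism.
Training is reproducible to floating-point determinism of the BLAS in use:
one seed fixes initialization, shuffling, augmentation and dropout.

## Known limitations

* Only the `tiny_cnn` backbone is instantiable; the twelve ImageNet
  backbone configurations validate but require an external pretrained
  library by design.
* The R/BLAS network core is CPU-bound and desk-scale; it is not a general
  deep-learning framework and implements exactly the layers this
  architecture needs.
* Phantom realism is deliberately limited (above); conclusions about
  clinical EBUS data require clinical data.
* Video decoding is out of scope: cases enter as frame stacks with a
  manifest.
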