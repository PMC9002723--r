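---
title: "Fusing image sets with a permutation-invariant network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing image sets with a permutation-invariant network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Image fusion combines several co-registered views of one scene — an MRI and a
PET slice, an infrared and a visible frame, a bracketed exposure stack, a
stack of differently focused shots — into one composite that keeps each
source's salient content. Two properties make the general problem awkward for
ordinary convolutional networks: the number of inputs N varies from scene to
scene, and the inputs form an unordered set, so the output must not depend on
the order in which they are presented.

`setfuse` implements a fusion network built around a *max-decomposition*: a
set function is realized as `f(X) = gamma(max_i phi(x_i))`, where `phi` maps
each input into a latent feature space, the element-wise max over the set
collapses it, and `gamma` decodes the fused image. Because max is symmetric
and blind to duplicates, the construction is permutation-invariant and
arity-agnostic by design rather than by training.

## Network

Every input luminance plane is a *stream*. Eight fusion blocks are arranged
in two phases of four, joined by a three-layer bottleneck, with a two-layer
tail. A fusion block applies one shared `conv 3x3 -> ReLU -> batch norm` to
every stream (the *batch mechanism*: one kernel regardless of N), pools the
per-stream features by element-wise max, and concatenates the pooled plane
back onto every stream, so each stream sees a summary of all others. Phase-2
blocks additionally concatenate a skip connection from phase 1, preserving
low-level detail: the pairing is the mirrored U-shape (block k's
pre-concatenation features feed block 9−k's concatenation), stored in
`net_config()` so alternatives remain testable — the pairing is shown only
pictorially in the source architecture diagram, so the mirror is this
package's reading of it. The tail reduces the last concatenation from 96 to
32 channels, max-pools across streams one final time, and reconstructs the
fused plane with a bare biased convolution, clipped to [0, 1].

Parameter counting follows the convention that reproduces the reference
architecture's printed table exactly: convolutions followed by normalization
carry no bias (the BN offset absorbs it) and contribute
`9*Cin*Cout + 2*Cout`; bare convolutions keep their bias
(`9*Cin*Cout + Cout`). With 32 base channels this yields 352 / 18,496 /
27,712 / 9,280 / 9,248 for the respective rows; see `count_parameters()`.
The printed count for the output layer (321 for a 3x3, 32-to-1 Conv+ReLU+BN)
is not reproducible under any standard convention (288 + 1 + 2 = 291), and
normalizing a single-channel output image is unusual, so the default tail is
a bare biased convolution (289 parameters); `net_config(tail_batchnorm =
TRUE)` restores the literal layout.

Numerical choices worth knowing:

* **Exactness of the symmetry guarantees.** Streams are convolved one at a
  time with fixed-height matrix products, so each stream's features are
  bit-identical no matter how many streams accompany it; permuting or
  duplicating inputs, or transferring a model trained with M streams to
  N ≠ M, changes the inference output by exactly zero bits. (A single
  stacked multiplication would let the BLAS pick different blocking — and
  rounding — for different N.) In training mode the batch-norm statistics
  are reductions over all streams, whose floating-point sums depend on
  summation order; exact invariance is therefore stated for inference.
* **Max subgradient.** Ties route the gradient to the first stream attaining
  the max; `pooling = "sum"` exists only for the ablation study.
* **Batch norm.** Statistics per feature over streams-as-batch times space;
  momentum 0.1, epsilon 1e-5, population variance in both the forward pass
  and the running-average update; inference uses running statistics.
* **Initialization.** He-normal kernels, unit gains, zero offsets; the
  output bias starts at 0.5 so that early training is not pinned against the
  [0,1] clamp (whose subgradient is zero outside the interval).
* **N = 1 is accepted** although a genuine fusion starts at N = 2; the
  single-stream path doubles as an identity check.

The gradients themselves come from a small reverse-mode tape over base-R
matrix operations; every pullback is pinned against central finite
differences in the test suite (relative error well under 1e-4).

## Losses

Supervised tasks (multi-exposure, multi-focus) use
`0.5 * MAE + 0.5 * (1 - MEF-SSIM) + 2e4 * L_EWC`; unsupervised tasks
(medical, infrared/visible) use `1 * (1 - MEF-SSIM) + 2e4 * L_EWC`, with the
EWC weight zero for the first task trained. The advisory range 1e4..3e4 for
the EWC weight is enforced as a warning, not an error.

MEF-SSIM is the no-reference structural quality index for fused images. For
every 8x8 sliding window (stride 1), each source patch is decomposed into
mean, contrast `c_k = ||x_k - mu_k||` and unit structure `s_k`; the desired
patch has the strongest contrast among the sources (`max_k c_k`) and the
renormalized, contrast-weighted mean structure (weights `c_k^p`). The fused
window is compared with this desired patch by a mean-removed
structure/contrast similarity with stability constant `C = (0.03 L)^2`;
omitting the luminance term makes the score exactly invariant to global
intensity offsets of the fused image. The weighting exponent is not printed
in the index's original description as used here, so `p = 4` is frozen in
`mef_ssim_params()` and exposed as a parameter; windows in which every
source is constant score 1 exactly when the fused window is constant too
(the stability constant handles this limit without special-casing, with
1e-12 regularizers guarding the structure normalizations). Source-order
invariance is exact up to the floating-point summation order of the
weighted-structure average (the max-contrast term is exact).

## Continual learning

Tasks are trained sequentially. After task n, the diagonal Fisher importance
`Omega_i = mean_d (dL(d, theta*)/d theta_i)^2` is estimated on a data subset
(default 50 sets; the per-example task loss without its EWC term, batch-norm
in training mode but with frozen running statistics, so the model is
bit-identical afterwards). Importances add across tasks and the anchor is
replaced by the latest trained parameters — the pooled-accumulation reading
of the training procedure; per-task anchor pairs are a known alternative the
package does not implement. Task n+1 then minimizes its loss plus
`lambda_EWC * sum_i Omega_i (theta_i - theta*_i)^2`. The penalty factor eta
defaults to 1 inside `ewc_penalty()` because the task-level lambda (2e4)
supplies the weighting once; a quadratic (squared-difference) penalty is
used throughout — it is the standard EWC form and the only one bounded
below. Optimization is Adam (beta1 0.9, beta2 0.99), batch size 1, learning
rate 1e-4 halved every 5e4 iterations with the iteration counter running
across tasks.

The default curriculum order is infrared/visible, medical, multi-exposure,
multi-focus with epochs (200, 300, 270, 3): the source material numbers
medical as task 1 in one place and names infrared/visible the first-trained
task in another, so the order is configurable and the package defaults to
the reading in which infrared/visible trains first (it is the task whose EWC
weight is explicitly zero).

## Synthetic data

The multi-focus simulator mirrors the mask-based defocus recipe: a frame is
partitioned into M in {2..8} binary complementary masks P_i; the clear image
is Gaussian-blurred with one sigma drawn from U[1, 2] per set (kernel radius
`ceil(3 sigma)`, mirror-reflected borders; these border/radius choices are
the package's own, as is the per-set rather than per-image sigma); each
defocused variant is `D_i = I_clear P_i + I_blur (1 - P_i)`, selected
pixel-for-pixel so that `sum_i D_i P_i` reconstructs the clear image
*exactly* — the simulator's invariant and an upper-bound oracle for any
fusion model. Masks come from coarse "basal" partitions of the frame into
1-4 connected regions intersected with free-form "shape" masks; the original
213 hand-made shape masks are not published, so the package regenerates the
same role procedurally (superellipse figures covering 15-60% of the frame),
and composition to more than the 8 intersection pieces, where needed, splits
the largest piece along its pixel ordering (how the original recipe reaches
M > 4 parts is unspecified). The reference corpus is 3000 sets of 128x128
patches; tests and the bundled studies use much smaller frames.

Because no external imagery ships with the package, `make_synthetic_raw()`
provides textured stand-ins (gradients, figures, sinusoids, filtered noise)
for natural-image crops, and `make_exposure_set()` renders a latent radiance
map at K log-spaced gains with sensor clipping plus a tone-mapped reference.
These emulate the *structure* of the real corpora — complementary sharp
regions, complementary well-exposed regions, a reference that no single
source equals — but not natural-image statistics, sensor noise,
misregistration, or demosaicing artifacts. Passing tests on them validates
the algebra and the optimization machinery, not full-scale benchmark
quality on real photographs.

## Scaled-down studies

Two qualitative findings are reproduced at desk scale with
`retention_study()` and `pooling_study()` (frozen conditions: 16x16 frames,
8 base channels, 16 training and 8 held-out sets, 3-frame exposure stacks,
focus sets with 2-3 variants, Adam at 3e-3, 500 + 500 and 200 iterations
respectively). The learning rate is raised above the full-scale 1e-4 so the
first task reaches its toy-scale plateau within the iteration budget —
retention is only measurable once the first task has actually converged;
with an undertrained first task, second-task training still *improves* it
and there is no forgetting to prevent. Under these conditions, training the
focus task after the exposure task costs the exposure task a clear drop in
held-out MEF-SSIM without EWC, while with EWC the drop is near zero, at the
price of a somewhat slower-learning focus task; and the max-pooling
aggregator beats sum pooling on the exposure task. Both studies are
deterministic per seed; the acceptance script reports their numbers, and the
test suite asserts only the directions.

## Color

Networks and losses operate on luminance only. RGB inputs are decomposed
with the BT.601 full-range (JPEG) YCbCr matrix — the variant is not
specified by the method, and BT.601 full range is the standard for 8-bit
stills; the choice is pinned in one internal constant. Fused chroma is the
weighted rule `Cf = sum_i C_i (C_i - tau) / sum_i (C_i - tau)` with
tau = 128, falling back to tau when the denominator vanishes (|den| < 1e-8
guards float noise): saturated chroma outvotes washed-out chroma, and
grayscale sources (neutral chroma) contribute nothing. Luminance lives on
[0, 1]; chroma stays on the 8-bit [0, 255] scale so the rule applies
literally. 16-bit files are rescaled by 1/65535 on reading; TIFF output can
be written at 16 bits, PNG output is 8-bit (a limitation of the underlying
writer).

## Known limitations

* No registration: inputs must already be aligned.
* The simulator's defocus is a single global Gaussian, not a depth-dependent
  point-spread function; no motion blur, no bokeh.
* Exact-zero symmetry guarantees hold for inference; training-mode batch
  statistics depend on stream summation order at machine precision.
* Checkpoints are R RDS archives (documented, versioned with a format tag),
  not portable to other frameworks.
* Full-scale benchmark comparisons against third-party fusion methods and
  metrics are out of scope; entropy, mutual information and MEF-SSIM are the
  shipped metrics, with the mutual-information convention chosen as the
  sum over sources of I(source; fused) — two near-identical sources then
  score about twice the fused image's entropy, matching how those numbers
  behave in the reference material's tables.
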