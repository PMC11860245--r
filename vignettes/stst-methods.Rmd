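---
title: "Two-stream metamer synthesis: models, losses and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stream metamer synthesis: models, losses and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stst)
```

## The problem

Vision experiments often need *dynamic* stimuli that preserve chosen
low-level properties of natural videos — luminance, contrast, color
distribution, and especially optical flow — while destroying high-level,
object-related content. `stst` synthesizes such "model metamers" by
optimizing each video frame so that its feature statistics inside a
two-stream reference model match those of one or more target videos. A
phase-scrambling baseline, a low-level feature analysis suite and
representational similarity metrics complete the toolbox, so generated
stimuli can be both produced and evaluated inside one package.

## The model

**Two streams.** A spatial module $S(x_t)$ sees one RGB frame
$x_t \in [0,1]^{H\times W\times 3}$; a temporal module $T(x_t, x_{t-1})$
sees a consecutive frame pair. Both expose named-layer activations
$A^\ell \in \mathbb{R}^{N_\ell \times M_\ell}$ (filters by spatial
locations, taken after the nonlinearity, spatial index row-major). The
algorithm is model-agnostic: any differentiable feature extractor works.

The default spatial stream is the VGG-19 convolutional architecture with
the canonical texture layers `conv1_1` … `conv5_1`. Pretrained weights are
an optional load (`make_vgg19_model(weights = ...)`); without them the
filters are seeded He-initialized draws, which is sufficient for the
package's desk-scale tests (random shallow filter banks are known to carry
useful texture statistics, and every test here runs on small seeded
"fixture" networks anyway). We use average rather than max pooling: it is
the customary choice in texture synthesis because it produces smoother
gradients with respect to the input.

The default temporal stream is an analytic multiscale spacetime-oriented
energy (MSOE) model, built rather than trained because trained motion-model
weights cannot be assumed available:

1. grayscale both frames (BT.601 weights $[0.299, 0.587, 0.114]$);
2. Gaussian pyramid (factor 2 per level, 3 levels by default, levels capped
   so a level never falls below the filter size);
3. quadrature pairs of oriented Gabor filters (4 orientations, carrier
   $f_0 = 0.25$ cyc/px, envelope $\sigma = 2$ px, radius 4) applied to both
   frames; a channel preferring displacement $v$ along direction $\theta$
   combines the two frames with temporal phase offset $2\pi f_0 v$. Two
   opposite directions per orientation plus a static channel give 12
   channels per scale;
4. quadrature outputs are squared and summed (motion energy), divisively
   normalized across channels, scaled by a gain, bilinearly upsampled and
   concatenated across scales into the `concat` layer.

Three numerical choices matter here. The Gabor kernels are mean-subtracted,
so their response to a constant image is zero, and the convolutions use
*circular* boundary conditions — together this makes the model exactly
invariant to global luminance offsets (an intended property of
motion-energy features), not just approximately so away from borders. The
divisive normalization constant (0.01) keeps the energies well-defined on
near-blank inputs. And the output `gain` (default 3) rescales the
dimensionless normalized energies so that temporal-stream Gram losses are
commensurate with spatial-stream losses: with unit gain the temporal term
was roughly 60-fold smaller on matched random inputs and contributed almost
no gradient, which silently reduces the two-stream objective to a
spatial-only one. This mirrors the common practice of rescaling feature
activations in style transfer so that loss terms with nominally equal
weights actually compete.

## The objective

Per layer, the **content loss** is
$\frac{1}{2 N_\ell M_\ell}\sum_{ij}(A_{ij} - \hat A_{ij})^2$ and the
**texture loss** is
$\frac{1}{2 N_\ell^2}\sum_{ij}(G_{ij} - \hat G_{ij})^2$ on Gram matrices
$G^\ell = \frac{1}{N_\ell M_\ell} A A^\top$. The total objective sums
$\alpha$-weighted content and $\beta$-weighted texture terms over the
spatial layers, $\theta$/$\lambda$-weighted terms over the temporal layers,
and an anisotropic total-variation penalty
$\frac{\omega}{HWC}\sum |\nabla g|_1$ (valid-neighbor sums at the frame
boundary). Weighted terms are summed over layers with unit per-layer
weights; a zero weight disables its term entirely, and each term can be
routed to a different target video — routing spatial texture to one video
and temporal texture to another is spatiotemporal factorization.

Defaults follow the reference setting: $\beta = \lambda = 1$,
$\alpha = \theta = 0$ (pure texture metamers), $\omega$ per octave
$(0.05, 0.1, 0.5)$.

## The optimization loop

Each frame is synthesized by plain gradient descent
$g_t \leftarrow g_t - \eta\, \partial L / \partial g_t$ — gradients are
taken with respect to the *current* generated frame only, with the previous
generated frame entering the temporal stream as a fixed input — inside a
coarse-to-fine octave loop: sizes $H_o = \lfloor H \sigma^o \rfloor$ with
$\sigma = 1.5$, octaves $(-2, -1, 0)$, iterations $(250, 750, 1000)$ and
learning rates $(0.001, 0.003, 0.005)$ by default. Truncation (not
rounding) is the integer conversion: it reproduces both reference
resolutions $640 \to 426 \to 284$. Gradients are normalized per channel by
their standard deviation over space (guard $\varepsilon = 10^{-8}$);
pixels are clamped to $[0,1]$ after every step so frames remain
displayable (the range constraint is otherwise unspecified); the estimate
is bilinearly upsampled between octaves, and content-loss targets are
re-rendered at each octave while texture targets only need the
size-agnostic Grams.

Temporal coherence is preconditioned in two ways. Each frame starts from
the blend $g_t \leftarrow \varphi g_{t-1} + (1-\varphi)\mu$,
$\mu \sim U(0,1)$, with $\varphi = 0.95$ (the very first frame is pure
noise, as it has no predecessor). And the whole target is mirror-padded:
its first $\xi = 5$ frames are time-reversed and prepended, the
corresponding outputs discarded, so the emitted frames all start from a
converged temporal context. Temporal loss terms are skipped at the very
first padded frame (no previous frame exists); with $\xi \ge 1$ this only
ever affects discarded frames.

After optimization each frame passes through a 3D color-distribution
transfer toward the routed reference frame (iterative distribution
transfer: random RGB rotations + sorted quantile matching of the rotated
marginals, 20 sweeps by default), followed by a regraining step that
reduces transfer grain by pulling the result's spatial gradients back
toward the optimized frame (Jacobi relaxation, 50 iterations, equal data
and gradient weights). Two package-specific choices: all frames of one run
share a single rotation sequence — redrawing rotations per frame adds
visible temporal color flicker — and in factorization mode the color
reference defaults to the spatial-texture target, on the view that the
spatial stream owns appearance (configurable via `color_reference`).

## The phase-scrambling baseline

`stps_generate()` implements the three-step comparison method: (1) one
random Hermitian-symmetric phase field per channel added to every frame's
2D spectrum (the same field across frames), (2) a 3D phase randomization of
the full spatiotemporal volume per channel, (3) per-frame color transfer
toward the original frame. Realness is guaranteed by drawing phases as the
phase of the FFT of a real noise field; DC phases are reset so means are
untouched. Amplitude spectra are preserved exactly, which the tests assert
at rtol $10^{-6}$ on the *unclipped* output; clipping to $[0,1]$ happens
between scrambling and color transfer.

## Feature analysis

Per frame: mean intensity over $H, W, C$; contrast as the *population*
standard deviation of the grayscaled frame. Per frame pair: mean absolute
pixel change; dense optical flow summarized by the arithmetic mean
magnitude and mean angle (radians in $[0, 2\pi)$, 0 = rightward, increasing
toward downward). A circular-mean option exists for the angle because the
arithmetic mean is degenerate for motion near the $0/2\pi$ wrap — the
arithmetic form stays the default for continuity with common practice, and
analyses that compare direction time courses should use
`circular_mean = TRUE`.

Optical flow is computed by a Farnebäck-style polynomial-expansion
estimator implemented in this package (no dense-flow implementation exists
in the surrounding R stack): quadratic local models under a Gaussian
applicability, displacement solved per pixel from the averaged
normal equations, refined over 10 iterations per level on a 5-level,
factor-0.5 pyramid with a 13-pixel averaging window, neighborhood 5 and
derivative smoothing 1.1 — the conventional parameterization for this kind
of feature analysis. A small relative ridge on the 2×2 normal matrix keeps
the solve well-posed under the aperture problem (pure 1-D structure like a
grating), where it degrades gracefully to normal flow. The estimator is
validated against fixtures with exactly known motion rather than against a
reference binary.

Color statistics use a $16^3$-bin joint RGB histogram pooled over frames
(additive smoothing $10^{-9}$) for KL divergences, and seeded k-means
($k = 5$) for palettes.

## Similarity metrics

`linear_cka()` is centered kernel alignment with a linear kernel, computed
in feature space ($\|Y_c^\top X_c\|_F^2 / \|X_c^\top X_c\|_F
\|Y_c^\top Y_c\|_F$) and tested for equality against the centered-Gram
HSIC form; activation tensors are reshaped with spatial locations as
samples. `ssim()` follows the standard measure (11×11 Gaussian window,
$\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$, dynamic range 1, grayscale for
RGB inputs, averaged over fully valid windows) and agrees with a reference
implementation to $10^{-6}$. `cssim()` is the next-frame-prediction
variant $(1 - \mathrm{SSIM}(f_{t-1}, \hat f_t)) \cdot
\mathrm{SSIM}(f_t, \hat f_t)$: predictions that copy the previous frame
score exactly zero. `sliding_cka()` applies CKA over 5-frame windows with
1-frame hop, for video-model activation sequences.

## Synthetic fixtures and what the tests show

All tests run on seeded generators with analytically known ground truth:
`drifting_grating()` (rigid sinusoid, known velocity),
`translating_texture()` (band-limited RGB noise translating toroidally —
translation is a Fourier phase shift, so global statistics are conserved to
machine precision and the true flow field is spatially uniform; direction
and speed may vary per frame pair) and `colored_blobs()` (static, exact
palettes). The fixture channels are kept strictly inside $[0,1]$ so no
clamping ever breaks the conservation identities.

The headline qualitative property — synthesis preserves the optical-flow
time course where phase scrambling destroys it — is asserted at desk scale
on 20×20, 10-frame textures whose motion direction switches mid-sequence
(two epochs). The epoch structure matters: a texture translating rigidly at
constant velocity concentrates its spatiotemporal spectrum on a single
plane, and *any* amplitude-preserving phase randomization then yields
another stimulus with essentially the same motion statistics — scrambling
only destroys motion that is nonstationary, as natural motion is. For this
comparison the synthesis runs a single octave (250 iterations,
$\eta = 0.04$, $\omega = 0.05$) with the fixture spatial net and the MSOE
stream, and disables the color-transfer stage: at 400-pixel frames with a
loosely matching random spatial net, the per-frame color warp is large and
frame-varying, and the flicker it adds dominates the flow measurement (the
full-scale pipeline's color transfer is a small correction; its documented
contribution is to color and contrast, not to flow). The scrambling
baseline keeps its complete three-step definition. Flow-angle time courses
are compared by Pearson correlation using circular-mean angles.

What passing these tests does *not* show: that the desk-scale fixture
networks produce perceptually convincing metamers of natural videos (that
requires pretrained spatial weights and the full octave schedule), nor that
the quantitative effect sizes of full-scale experiments are reproduced.
The tests verify the algorithmic machinery — losses, gradients, schedules,
spectral operations, flow recovery, metric identities — exactly, and the
headline ordering qualitatively.

## Problem sizes and runtime

The test suite uses 8–48 px frames, 2–10 frames per video, fixture networks
(≤ 8 filters) and a 2-scale MSOE; the heaviest single check (the 5-seed
synthesis-vs-scrambling comparison) runs in a few minutes on one CPU. The
reference full-scale setting (360×640, 120 frames, three octaves, VGG-19)
is supported by the same code paths but is hours-scale work best run on
numerical accelerators, which is out of scope for the test suite.

## Known limitations

- No video-container I/O: videos are lossless PNG frame directories.
- The analytic MSOE approximates, but is not, a trained optical-flow
  network; its filter bank parameters are exposed in `msoe_params()`
  rather than asserted as ground truth.
- Pretrained VGG-19 weights are not shipped; random filters are a weaker
  spatial prior.
- The flow estimator targets dense smooth motion; it is not a
  general-purpose replacement for production optical-flow libraries on
  large displacements or occlusions.
- Gradient descent is the only optimizer (matching the published update
  rule); momentum methods could be added behind the config without
  changing the objective.
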