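---
title: "Unrolled recurrent U-Net reconstruction for cardiac cine MRI: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unrolled recurrent U-Net reconstruction for cardiac cine MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinerecon)
```

## The reconstruction problem

Cardiac cine MRI acquires a short movie of the beating heart. Each frame is
measured in k-space (the spatial-frequency domain) through several receiver
coils, and to keep the breath-hold short only a subset of phase-encode lines
is acquired. Reconstruction solves the inverse problem

$$\hat x = \arg\min_x \;\|y - A x\|_2^2 + \lambda R(x), \qquad A = M F S,$$

where $x \in \mathbb{C}^{T\times H\times W}$ is the complex image sequence,
$S$ the coil sensitivity maps, $F$ the (centered, orthonormal) 2D Fourier
transform per frame and coil, $M$ the binary line mask, and $R$ a
regularizer. This package implements an unrolled solver: a fixed number of
cascades, each consisting of a learned image-domain regularization step (a
convolutional recurrent U-Net block) followed by a closed-form k-space
data-consistency (DC) step

$$x_{i+1} = A^\dagger \Lambda A' z_i + \tfrac{\lambda_0}{1+\lambda_0} A^\dagger y,
\qquad \Lambda_{kk} = \begin{cases} 1 & k \notin \Omega\\
\tfrac{1}{1+\lambda_0} & k \in \Omega,\end{cases}$$

where $\Omega$ is the set of acquired k-space indices. As
$\lambda_0 \to \infty$ the acquired samples are kept exactly ("hard" DC,
the default); the network only interpolates the unacquired region. The
prime on $A'$ indicates one deliberate reading: the Fourier/coil part of
the forward model is applied *without* the mask projection, so the
network's k-space content at unacquired locations is retained rather than
discarded — a literal masked operator would throw away exactly the
information the regularizer was asked to create.

### What "preserving the measured samples" means with multiple coils

The conjugate coil combination $S^\dagger(\cdot)$ is a pixelwise projection
onto the span of the sensitivity vectors. Re-expanding the *combined* image
through $F S$ therefore does not reproduce per-coil k-space exactly (the
residual is the component orthogonal to the sensitivity span, typically
$\sim 10^{-2}$ for an untrained network). The representation in which hard
DC preserves the data *exactly* is the blended per-coil k-space itself, so
`crunet_forward()` and `reconstruct_slice()` return it (`kspace`, the
$y_\mathrm{rec}$ of the pipeline) alongside the combined image. All
preservation guarantees in the tests are stated on that object; image-level
idempotence holds exactly for measurement-consistent inputs.

## The network

Each cascade block is a two-level U-Net over the `(H, W, 2, T)` real view
of the sequence (real/imaginary channels):

1. **z-score normalization** of the whole sample (mean and standard
   deviation over all frames, pixels, channels), inverted at the block
   exit; the moments are treated as constants during backpropagation.
2. a **head convolution** (2 → C channels, ReLU),
3. a **level-1 encoder recurrent unit** (forward in time, dilation $d_1$),
4. a strided **Conv(2+1)D downsampling** layer (C → 2C),
5. a **level-2 encoder recurrent unit** (forward, dilation $d_2$),
6. a **bidirectional bottleneck unit** (dilation $d_3$) with a standard
   1×1-convolution side branch, closed by a Conv(2+1)D layer,
7. a **level-2 decoder recurrent unit** (backward in time) on the skip
   merge of bottleneck and encoder features,
8. nearest-neighbour ×2 **upsampling** plus Conv(2+1)D (2C → C),
9. a **level-1 decoder recurrent unit** (backward) on the second skip
   merge,
10. a **tail convolution** back to 2 channels, un-normalization, and a
    residual connection around the whole block.

The recurrent unit maintains a hidden state across the cine frames:

$$H_t = \sigma(W_l * x_t + W_t * H_{t\mp1} + W_i * F_t^{(i-1)} + B),$$

with a zero initial hidden state and ReLU activation; the bidirectional
version sums a forward-running and a backward-running unit. $W_i$
convolves the same level's merged feature map from the *previous cascade*,
so information also flows along the unrolled iteration axis — each level's
merged encoder+decoder output (and the bottleneck output) is stored in the
cascade state and fed to both directional units of the next cascade.

**Weight sharing across cascades.** The unit weights carry no cascade
index: the same block parameters are applied at every cascade. That is
what makes the $W_i$ term a recurrence *over iterations* rather than a set
of per-cascade skip connections, and it keeps the parameter count
independent of the unrolling depth (asserted by a test).

**Conv(2+1)D and temporal circular padding.** Spatio-temporal convolutions
are factorized into a per-frame 2D convolution followed by a temporal 1D
convolution. A cine sequence covers exactly one cardiac cycle, so the last
frame precedes the first; all temporal convolutions therefore use circular
padding by default (`use_temporal_padding`), which makes each layer exactly
equivariant to cyclic frame shifts. Disabling it (zero padding) is an
ablation switch.

**Dilations.** The level-1 operations use standard convolutions
($d_1 = 1$) to preserve fine detail; level 2 and the bottleneck enlarge the
receptive field with dilations $(d_2, d_3)$, default $(2, 4)$, also
selectable as $(1, 1)$ or $(3, 5)$. Side branches always use standard
(undilated) 1×1 convolutions.

**Conv3D baseline.** `variant = "unet3d"` replaces every recurrent unit
with a 3D convolution block of matched width (implemented exactly as
$k_t$ spatial convolutions of temporally shifted copies), keeping the
topology, normalization and DC identical. It serves as the
non-recurrent baseline.

### Choices the architecture description leaves open

* *Decoder direction*: the two directional units of a level are placed as
  encoder-forward / decoder-backward, satisfying "opposite propagation
  directions"; interleaving them differently would be an equally literal
  reading.
* *Cascade state*: the feature map passed to the next cascade is the sum
  of the level's encoder and decoder unit outputs (the "merged" output);
  the bottleneck passes its bidirectional sum after the side branch.
* *Skip merge*: elementwise addition by default, mirroring the
  bidirectional summation semantics; concatenation is available
  (`skip_merge = "concat"`).
* *Residual connection* around each block: included; it makes an
  untrained block near-identity, which stabilizes the unrolled pipeline.
* *Channel width and kernel sizes*: not fixed by the architecture
  description; defaults are 48 base channels and 3×3 spatial / length-3
  temporal kernels, both configurable.
* *Odd image sizes*: inputs are zero-padded to even height/width before
  the down/upsampling pair and center-cropped back at the block exit.
* *Initialization*: uniform fan-in (PyTorch-style) for all kernels, zero
  biases, zero initial hidden states and cascade features; fully seeded.

## Training objective

The loss on a normalized sample is

$$L = \lambda_1\,\mathrm{MSE}(F I_\mathrm{rec}, F I_\mathrm{gnd})
    + \lambda_2\,\mathrm{L1}(I_\mathrm{rec}, I_\mathrm{gnd})
    + \lambda_3\,\mathrm{MSE}(I_\mathrm{rec}, I_\mathrm{gnd})
    + \lambda_4\,(1 - \mathrm{SSIM}(I_\mathrm{rec}, I_\mathrm{gnd})),$$

with defaults $\lambda_{1..4} = (0.25, 0.5, 0.5, 1)$, everything computed
on the two-channel real view; SSIM is evaluated separately on the real and
imaginary channels and averaged. With the orthonormal Fourier convention
the k-space MSE equals the image-domain MSE (Parseval) — the term is still
computed through the FFT, and the identity doubles as a test oracle. SSIM
uses an 11×11 Gaussian window ($\sigma = 1.5$), stabilizers
$C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$ with $L$ the maximum absolute
ground-truth channel value per sample, and same-size zero-padded windows
(the window convention is not fixed by the loss definition; these are the
field's standard defaults, exposed as arguments).

Training uses AdamW (decoupled weight decay 0.01), batch size one slice,
warm-up plus cosine-annealing learning rate (defaults: peak 3e-4, floor
1e-4, 10 warm-up epochs), and global gradient-norm clipping at 1.0 — the
clip is a stabilizer for the recurrent units; measured gradient norms at
initialization are well below 1, so it does not throttle learning. Each
sample is normalized by the peak magnitude of its own zero-filled coil
images (`maxabs_normalize()`), and the ground truth is scaled identically
for the loss.

Everything is trained with the package's own reverse-mode differentiation
engine (a flat tape over array tensors with compiled im2col/GEMM
convolution kernels); its gradients are verified against central finite
differences for every operator class in the test suite.

## Sampling masks

`make_mask()` reproduces uniform Cartesian undersampling with a central
ACS block: every `accel`-th row (0-based, plus `offset`) union a centered
block of `acs_lines` fully sampled rows; the mask is constant along the
readout axis and shared by all frames. `effective_acceleration()` reports
rows / acquired-rows — e.g. 192 rows at nominal R = 4 with a 24-line ACS
give 66 acquired rows, effective acceleration 192/66 ≈ 2.9. A nominal
factor of 24 is implemented as period-24 uniform sampling, the same rule
as the other factors; the alternative "gap of 24, period 25" reading is
reachable as `accel = 25`.

## Evaluation and the dynamic region

PSNR and SSIM are computed on magnitude sequences with the per-sequence
maximum ground-truth magnitude as data range (the metric input convention
is not standardized; this one is documented and consistent). Moving
tissue is isolated by the temporal standard deviation of the ground-truth
magnitude: pixels above the 90th percentile (strict inequality, percentile
over all pixels of the slice) form the *dynamic region*, the rest the
*static region*. Region PSNR restricts the MSE to the region's pixels;
region SSIM averages the full-image local SSIM map over the region, since
SSIM windows are not defined on bare point sets — windows near region
boundaries therefore also see out-of-region pixels. The squared errors of
the two regions partition the global squared error exactly, which the
tests assert to machine precision.

## The synthetic phantom

`make_phantom()` generates the statistical structure the method relies on,
not anatomy: a background ellipse with seeded static elliptical
structures, plus a "myocardial" annulus around a bright pool whose radii
oscillate as $r(t) = r_0(1 + a\sin(2\pi (t-1)/T))$ — motion with period
exactly $T$, so the circular-padding assumption is valid by construction.
A smooth low-order polynomial phase makes the object genuinely complex;
magnitudes are scaled to unit maximum so the max-abs normalization scale is
≈ 1 on clean data. `make_coil_maps()` places Gaussian-magnitude,
linear-phase profiles at equidistant angles and normalizes them to unit
sum of squares. `simulate_acquisition()` adds complex Gaussian k-space
noise *before* masking, so the fully sampled and undersampled copies share
one realization. What the phantom does **not** emulate: anatomy and
tissue contrast, through-plane motion, arrhythmic (non-periodic) cycles,
motion/flow artifacts, and realistic coil noise correlations — so passing
tests demonstrate correctness of the pipeline and learnability of the
inverse problem, not clinical image quality.

Default conditions: 12 frames per cycle, 8 coils, 15% radius modulation,
unit-peak magnitudes; noise and matrix size are set per experiment.

## The desk-scale training experiment

`micro_experiment()` is the package's end-to-end check that the unrolled
network actually learns: 2 cascades, 8 base channels, 8 frames of 64×64
with 4 coils, nominal R = 4 with an 8-line ACS block (effective ≈ 2.9),
k-space noise 0.005, 20 training and 4 validation slices, 30 epochs of
batch size one — 600 optimizer steps, about ten minutes on one CPU core.
For this short schedule the learning rate is scaled to a peak of 1e-3
(floor 1e-4, 2 warm-up epochs); the full-scale defaults in
`train_config()` are tuned for runs two orders of magnitude longer and
would leave a few-hundred-step run far from convergence. Reported quantities: validation PSNR of the
zero-filled baseline and of the reconstruction, their gap, the SSIM, and
the ratio of final to initial training loss (the initial loss is measured
by evaluating the untrained network on the training set). The problem
sizes here — and the deliberately small instances used throughout the test
suite — were chosen so the whole suite runs comfortably on a laptop core;
they are stated in each test.

## Numerical conventions and degenerate inputs

* Fourier transforms are centered and orthonormal; both directions are the
  same ifftshift–FFT–fftshift sandwich (the order matters for odd sizes).
* The z-score clamps the standard deviation at 1e-8, so constant inputs
  normalize to zero and round-trip exactly.
* `psnr()` reports a capped 100 dB for identical inputs rather than
  infinity.
* Empty regions in `region_metrics()` yield `NA` sentinels; empty masks,
  all-zero k-space, non-finite inputs, and shape mismatches are rejected
  with errors.
* The learnable DC weight is stored as $\log \lambda_0$ (initialized at
  $10^4$), keeping it positive under gradient updates; hard DC is the
  exact $\lambda_0 \to \infty$ limit, implemented as replacement rather
  than a large finite blend.
* Training aborts with a diagnostic on a non-finite loss; checkpoints
  store the weights and configuration, and a fixed master seed reproduces
  a training run bit for bit on one machine.

## Known limitations

* Coil sensitivity maps are inputs; estimating them from data (ESPIRiT
  and relatives) is out of scope.
* Only Cartesian row-undersampling with a frame-fixed mask is supported;
  non-Cartesian trajectories, partial-Fourier handling and frame-varying
  masks are not.
* The CPU implementation is intended for desk-scale experiments; the
  architecture matches the method, but full-scale training (hundreds
  of epochs on hundreds of multi-coil slices) is outside what this
  package is meant to do.
* SSIM here uses zero-padded same-size windows; implementations that crop
  the window margin will differ slightly near image borders.
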