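# cinerecon

Reconstruction of dynamic cardiac cine MRI from undersampled multi-coil
k-space data, for researchers who want a fully inspectable, CPU-scale
implementation of an unrolled deep reconstruction pipeline in R — from the
acquisition model to a trained network — with every moving part testable
against closed-form oracles.

## The method

Accelerated cine MRI measures only a subset of phase-encode lines of each
frame through several receiver coils:

```
y = A x + noise,      A = M ∘ F ∘ S
```

with `x ∈ C^{T×H×W}` the complex image sequence, `S` the coil sensitivity
maps, `F` the centered orthonormal 2D Fourier transform, and `M` a binary
line mask (uniform Cartesian sampling plus a fully sampled central ACS
block, fixed across frames). Reconstruction unrolls a fixed number of
cascades, alternating

1. a **learned regularizer**: a two-level convolutional recurrent U-Net
   block acting on the real/imaginary channel view, whose recurrent units
   propagate hidden state both across the cine frames (forward and
   backward in time) and across the cascade index, with factorized
   Conv(2+1)D layers using temporal circular padding (the cardiac cycle is
   periodic), dilated convolutions at the deeper levels, z-score
   normalization per block, and a residual connection; and
2. **closed-form data consistency** in k-space: acquired samples are kept
   exactly (hard mode, the λ₀ → ∞ limit) or blended as
   `(k_z + λ₀ y)/(1 + λ₀)`, with everything else taken from the network.

Training minimizes `λ₁·MSE(F·rec, F·gnd) + λ₂·L1 + λ₃·MSE +
λ₄·(1 − SSIM)` with weights (0.25, 0.5, 0.5, 1), using AdamW and a
warm-up/cosine learning-rate schedule. Evaluation reports PSNR/SSIM
globally and separately for the *dynamic region* — pixels whose
ground-truth temporal standard deviation exceeds the 90th percentile, a
proxy for moving cardiac tissue.

A Conv3D baseline (`variant = "unet3d"`) replaces every recurrent unit
with a 3D convolution of matched width; ablation flags remove the side
branches, the temporal circular padding, or the cross-cascade recurrence.

There is no deep-learning framework underneath: the package ships its own
reverse-mode differentiation engine (flat tape over array tensors,
compiled im2col/GEMM convolution kernels via Rcpp/RcppArmadillo), whose
gradients are verified against finite differences in the test suite. A
synthetic generator (`make_phantom()`, `make_coil_maps()`,
`simulate_acquisition()`, `make_dataset()`) produces cyclically beating
multi-coil phantoms with known ground truth, so the whole pipeline trains
and validates without any external data.

## Worked example

```r
library(cinerecon)

# an undersampling mask: 192 phase-encode rows, nominal R = 4, 24 ACS lines
m <- make_mask(192, 144, accel = 4, acs_lines = 24)
print(m)
#> sampling_mask: 192 x 144, nominal R = 4, ACS lines = 24
#>   acquired rows: 66 (effective acceleration 2.909)

# a beating 12-frame phantom with 8 coils, and its acquisition
sp  <- phantom_spec(T = 12, H = 64, W = 64, n_coils = 8, seed = 7)
ph  <- make_phantom(sp)
S   <- make_coil_maps(sp)
mk  <- make_mask(64, 64, accel = 4, acs_lines = 8)
acq <- simulate_acquisition(ph$img, S, mk, noise_sigma = 0.005, seed = 7)

# the aliased zero-filled baseline the network starts from
zf <- zero_filled_recon(acq$y, S, mk)
round(c(psnr = psnr(zf, ph$img), ssim = ssim_eval(zf, ph$img)), 3)
#>   psnr   ssim
#> 24.411  0.787

# dynamic-region analysis of the ground truth
dm <- dynamic_mask(ph$img)
mean(dm$dynamic)          # fraction of pixels flagged as moving
#> [1] 0.1000977
```

The flagged pixels trace the oscillating annulus — the 90th-percentile
rule marks 10% of the image as dynamic, and on this phantom those pixels
sit on the moving "myocardium".

The end-to-end experiment (synthetic dataset → 30 epochs of AdamW → 
validation) runs as one call:

```r
res <- micro_experiment(seed = 1)
round(c(zf = res$zf_psnr, rec = res$rec_psnr, gain = res$psnr_gain,
        ssim = res$rec_ssim, loss_ratio = res$loss_ratio), 2)
#>         zf        rec       gain       ssim loss_ratio
#>      24.60      38.21      13.61       0.98       0.17
```

The trained 2-cascade, 8-channel network recovers ~14 dB over the
zero-filled baseline on held-out slices, and the training loss ends at a
sixth of the untrained network's loss.

## Command line

A thin CLI over the same functions lives at `inst/cli/cinerecon`
(`simulate | mask | train | reconstruct | evaluate`), e.g.

```sh
Rscript inst/cli/cinerecon mask --rows 192 --cols 144 --accel 4 --acs 24
Rscript inst/cli/cinerecon simulate --out data --n-slices 10 --size 64x64 --coils 4 --accel 4 --acs 8
Rscript inst/cli/cinerecon train --train data --val data --epochs 5 --cascades 2 --channels 8
```

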