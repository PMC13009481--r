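---
title: "Thin-slab MRI restoration: degradation models, network, uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thin-slab MRI restoration: degradation models, network, uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrislab)
```

## The problem

High-resolution 3D MRI costs acquisition time, and long scans invite subject
motion. `mrislab` implements a unified pseudo-3D restoration framework for
the two resulting degradations: super-resolution reconstruction (SRR) of
volumes acquired with a reduced k-space matrix, and motion artifact
reduction (MAR) of volumes whose k-space lines were acquired in different
head positions. A single 2D convolutional backbone handles both tasks by
mapping a *thin slab* of `M` adjacent slices to the channel dimension, which
captures through-plane context at a small fraction of the memory and compute
of a true 3D network. An evidential regression head provides per-voxel
uncertainty that separates irreducible data noise from model uncertainty,
and a calibration layer turns slice-mean model uncertainty into predicted
SSIM/PSNR with 95% prediction intervals — an estimate of reconstruction
quality when no ground truth exists.

## Degradation simulators

**Low resolution by k-space truncation.** A volume is transformed with a 3D
FFT, the spectrum is truncated symmetrically about DC to the central
`dim/s` block per axis, and the result is inverse-transformed and rescaled
to [0, 1]. Scale factors are ordered FE × PE × SL (frequency-, phase-,
slice-encoding). Because scan time scales with the number of PE and SL
steps, the acceleration factor is `s_pe * s_sl`; FE sub-sampling discards
data without saving time. Truncation removes exactly `1 - 1/(s_fe s_pe
s_sl)` of the complex coefficients: 75% for 2×2×1, 50% for 1×1×2, 87.5% for
2×2×2. With `keep_matrix = FALSE` (the default, and what a genuine
low-resolution acquisition produces) the matrix shrinks and the voxels
grow; `keep_matrix = TRUE` zero-fills back to the original grid for
baselines that operate at the high-resolution matrix. Training pairs for
the network use the reduced matrix with learned upsampling — the network's
channel expansion (through-plane) and pixel-shuffle module (in-plane) carry
the super-resolution, so no interpolation enters the input path.

Conventions worth stating exactly: DC is centered by a circular shift of
`floor(n/2)`; for even dimensions the retained window along an axis of
length `n` is the 0-based half-open interval `[n/2 - n/(2s), n/2 + n/(2s))`,
which always contains the DC line. Divisibility of each dimension by its
factor is enforced, so the window never needs rounding. After the inverse
FFT the real part is taken; symmetric truncation of a real image's spectrum
is Hermitian up to the unpaired Nyquist line, and a check warns if the
residual imaginary magnitude exceeds 1e-8 of the signal.

**Motion artifacts by k-space splicing.** The simulator reproduces a
controlled periodic motion pattern rather than random motion, so artifact
severity is exactly reproducible. Time is counted in echo groups (EG) — a
block of consecutively acquired k-space lines (80 echoes by default); all
motion durations are integer multiples of EG. Starting from `Ts` at rest,
one period consists of a 9-EG leftward excursion (2 EG rotating, 5 EG held
at 5°, 2 EG rotating back), `Ts` at rest, the mirrored rightward excursion,
and `Ts` at rest again: 18 EG displaced per `18 + 2 Ts` EG of period. The
displaced fraction — the k-space corruption ratio — is therefore
`18/(18 + 2 Ts)`: 50%, 33%, 20% and 11% for `Ts` = 9, 18, 36, 72 EG. The
rotation ramps are modeled at the full displaced angle; this is what makes
the 18-EG-per-period accounting exact.

To corrupt a volume, the original is rigidly rotated (trilinear resampling,
zero fill outside the field of view; in-plane rotation about the slice
axis, through-plane "nodding" about the FE axis) once per distinct displaced
state. Each slice of each state is transformed to 2D k-space, and every
phase-encoding line is taken from the state active at its acquisition time.
Lines fill in centric order (outward from DC, ties to the lower index), and
the timeline advances continuously across slices, mimicking one 3D
acquisition; a per-slice restart is available as an option. The magnitude
image is taken after the inverse FFT and rescaled to [0, 1]. The simulator
reports both the periodic closed-form ratio and the realized ratio of the
finite fill (which includes the initial rest block and is therefore
slightly lower).

## Patch and slab geometry

High-resolution volumes are cut in-plane into 128×128 patches with 32-voxel
overlap; low-resolution inputs into 64×64/16 for in-plane scale 2 and
32×32/8 for scale 4 (for scale 1 the grids coincide). If an axis does not
tile exactly, the last patch is shifted to end at the boundary, locally
increasing overlap but never changing the patch size. Through-plane, every
`M`-slice window at stride 1 forms an input slab (`M` odd, at most 5);
consecutive slabs share `M - 1` slices, so each interior slice is restored
`M` times from different channel positions. The output slab carries
`N = M * s_sl` slices for SRR and `N = M` for MAR.

At inference, each output patch contributes its central region — half the
overlap is discarded per side, with ownership boundaries at the midpoint of
the overlap between neighbors, and edge patches keeping their outer borders.
Slab outputs grouped by start offset modulo `M` tile the slice axis exactly
into up to `M` candidate volumes; *self-ensemble* is the unweighted
voxel-wise average of these candidates. Boundary slices appear in fewer
than `M` candidates and average over however many exist — padding would
invent data. With an identity mapping in place of the network this whole
pipeline reproduces the input bit-exactly, which the test suite asserts for
every geometry in the studied grid; no feathered blending or flip/rotation
augmentation is used.

## Network

The restoration model is a thin-slab adaptation of the residual
channel-attention network (RCAN): a shallow 3×3 convolution takes the `M`
slab slices (as channels) to `n_feat = 64` features; `n_rg = 5` residual
groups of `n_rcab = 5` residual channel-attention blocks follow, each block
being conv–ReLU–conv gated by a squeeze-and-excite channel attention
(global average pool, bottleneck to `n_feat/reduction`, ReLU, expansion,
sigmoid) with a residual add; each group and the whole body carry skip
connections, the body skip reaching back to the shallow features. In-plane
super-resolution uses sub-pixel (pixel-shuffle) upsampling, one ×2 stage
for scale 2 and two for scale 4; the MAR path has none. The final
convolution emits `N` maps, or `4N` with the evidential head. Kernels are
3×3 except the 1×1 attention bottleneck; `reduction = 16` follows the RCAN
default (the bottleneck is 4 channels at 64 features). Weights use He
initialization from a recorded seed.

All layers are implemented natively in R: convolutions run as im2col + GEMM
so the arithmetic lands in BLAS, and every backward pass is hand-derived
and verified against finite differences in the test suite. Training uses
Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) under a cosine-decay learning rate
from 1e-4 to 1e-8 over 50 epochs with batches of 8 randomly drawn patches —
the reference protocol; scaled-down runs override the step count and
endpoints explicitly.

## Losses

The restoration objective is a Charbonnier term plus a weighted squared-SSIM
term, `L = L_Char + w1 * L_SSIM` with `w1 = 0.5`:

* `L_Char = mean(sqrt((HR - SR)^2 + eps))` with `eps = 1e-4`. The constant
  sits un-squared inside the root, so identical images give
  `sqrt(eps) = 0.01` — the loss's floor, not zero.
* `L_SSIM = mean(1 - SSIM_i^2)` over the patches `i`, squaring the
  per-patch mean SSIM to sharpen the penalty near 1. SSIM uses an 11×11
  Gaussian window (σ = 1.5), K₁ = 0.01, K₂ = 0.03, data range 1, evaluated
  on the valid region (borders cropped). Squaring per patch versus squaring
  the batch mean differ by well under 1e-3 in our regimes; the per-patch
  form is used.

With the evidential head the total becomes
`L_Char + w1 L_SSIM + w2 L_NIG` with `w2 = 1`, where `L_NIG = L_NLL +
lambda * L_Reg` is the Normal-Inverse-Gamma negative log-likelihood
(equivalently, the negative log Student-t predictive with 2α degrees of
freedom — the test suite exploits this equivalence as an independent
oracle) plus the evidence regularizer `|y - gamma| (2v + alpha)`. No
canonical value of `lambda` exists; the default is 0.01, configurable, and
chosen at the scale conventional in evidential regression. The prediction
compared by the image terms is the evidential mean `gamma`.

## Uncertainty and quality calibration

The network's four maps parameterize a Normal-Inverse-Gamma prior over the
per-voxel mean and variance. Its moments give the prediction `E[mu] =
gamma`, the aleatoric uncertainty `E[sigma^2] = beta/(alpha - 1)` and the
epistemic uncertainty `Var[mu] = beta/(v (alpha - 1))`; the identity
`epistemic * v = aleatoric` holds exactly and is asserted voxel-wise. The
positivity constraints (`v > 0`, `alpha > 1`, `beta > 0`) are built into
the head via softplus links, so they hold for arbitrary weights.

For quality estimation without ground truth, slice-mean epistemic
uncertainty `u` is regressed against slice SSIM (linear, `SSIM = a u + b`)
and PSNR (exponential, `PSNR = c exp(d u) + e`, reflecting PSNR's
logarithmic nature; the three-parameter form nests a flat asymptote, and a
log-linear fit initializes the Levenberg–Marquardt refinement). Prediction
intervals are classical for the linear model and delta-method for the
exponential one. Observations are pooled across subjects per slice;
predictors more than twice the fitted range from its midpoint trigger an
extrapolation warning rather than an error. Display rescaling of
uncertainty maps to [0, 1] is presentation only and never feeds
computation.

## The synthetic phantom

Every component is testable without external data through a deterministic
phantom: nested soft-edged ellipsoids (sigmoid falloff, positive layered
amplitudes so the background rescales to ~0 like air around a head) provide
low-frequency anatomy; a band-limited Gaussian random field (correlation
length `texture_scale` voxels, confined to the head support) provides
high-frequency texture that super-resolution can meaningfully recover;
optional Gaussian noise precedes the final rescale to [0, 1]. Identical
specs give bit-identical volumes. A constant volume rescales to all zeros
by convention (there is no contrast to preserve).

What the phantom does *not* emulate: MR contrast physics (T1/T2), bias
fields, coil sensitivities, anatomical variability across subjects, and
realistic noise correlations. Passing tests therefore demonstrate that the
algorithms are implemented correctly and that the learning machinery works
end to end — not that desk-scale training reaches the reconstruction
quality reported on real brain data, which requires full-scale training on
real volumes.

## Problem sizes and numerical choices

The test suite's scaled-down studies use 32×32×16 phantoms: the SRR study
trains a 1-group, 2-block, 16-feature network for 300 steps (batch 8,
cosine 1e-3 → 1e-5) on 8 phantoms with 1×1×2 down-sampling and `M = 3`, and
is compared against separable Catmull-Rom (tricubic) interpolation on a
held-out phantom; the MAR study trains the same backbone for 500 steps
(cosine 2e-3 → 1e-5) on 12 phantoms corrupted at `Ts = 9` EG with 5°
in-plane plus 5° through-plane rotation, using 2 echoes per EG so several
motion periods fit a small k-space (the corruption ratio depends only on
`Ts` in EG units, so the printed ratios are unchanged). Monte-Carlo
validation of the evidential moments uses 10⁶ NIG draws per hyperparameter
tuple and a 3-standard-error band.

Other conventions: volumes are arrays indexed (FE, PE, SL) with in-plane
operations on the first two axes and slabs along the third; the MAR
experiments of the reference protocol use axial-plane images, which
corresponds to permuting the volume before slab extraction; infinite PSNR
(identical volumes) serializes as the string `"inf"`; and all randomness —
phantom fields, weight initialization, batch order — flows from recorded
seeds, with RNG state restored after each use so library calls never
perturb user code.

## Known limitations

Only rotational motion is simulated (no translation or drift, no
through-scan random motion), matching the training model's scope;
real-world motion is more heterogeneous. The native network implementation
is single-threaded BLAS-bound and intended for method development and
desk-scale experiments, not full-scale training. Parallel-imaging
undersampling patterns, partial Fourier, and k-space noise injection are
out of scope of the degradation models.
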