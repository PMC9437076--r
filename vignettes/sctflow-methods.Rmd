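---
title: "Methods: structure- and flow-constrained cycle-consistent MR-to-CT translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure- and flow-constrained cycle-consistent MR-to-CT translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctflow)
```

## The problem

MR-only radiotherapy planning needs CT-like images: dose calculation requires
electron density, which MR intensities do not encode. A *synthetic CT* (sCT)
is an image generated from MR whose voxels are calibrated Hounsfield units
(HU), so it can stand in for a planning CT. `sctflow` implements a family of
cycle-consistent adversarial models for paired T2-weighted-MR-to-sCT
translation of pelvic axial slices, together with the full preprocessing,
dense-optical-flow, training and HU-space evaluation pipeline around them,
and a seeded phantom generator that makes every stage testable on a laptop.

## The four objectives

All four model variants share the same pair of generators
(`G_CT`: MR &rarr; sCT, `G_MR`: CT &rarr; sMR) and discriminators
(`D_CT`, `D_MR`) and differ only in the generator objective:

| variant      | objective                                                              |
|--------------|------------------------------------------------------------------------|
| `cyclegan`   | `L_GAN + 10 * L_cycle`                                                 |
| `structcgan` | `L_GAN + 8 * L_cycle + 2 * L_SSIM`                                     |
| `flowcgan`   | `L_GAN + 8 * L_cycle + 2 * L_flow`                                     |
| `sfcgan`     | `L_GAN + 6 * L_cycle + 2 * L_SSIM + 2 * L_flow`                        |

* **Adversarial term** — least-squares (LSGAN):
  `E[(D_MR(sMR) - 1)^2] + E[(D_CT(sCT) - 1)^2]` for the generators; each
  discriminator minimizes `E[(D(real) - 1)^2] + E[D(fake)^2]`, and the net
  discriminator loss averages the two modalities. Expectations are batch
  means.
* **Cycle consistency** — mean L1 between each input and its round-trip
  reconstruction, summed over modalities.
* **Structural similarity** — windowed SSIM with 11&times;11 uniform windows,
  `C1 = 0.0001`, `C2 = 0.009`, computed on a `[0, 1]` intensity scale; the
  loss is `1 - (SSIM_CT + SSIM_MR)/2` with per-window values averaged over
  all valid window positions and over the batch.
* **Flow consistency** — dense optical flow is estimated *in advance*
  between adjacent ground-truth axial slices (both directions); during
  training the synthesized slice `n` is warped towards each ground-truth
  neighbour and penalized by the mean L1 residual. The CT-side and MR-side
  terms are averaged.

Training alternates one generator update and one update of each
discriminator per step, uses Adam (`lr = 2e-4`, `beta1 = 0.5`,
`beta2 = 0.999`), a batch of 4 paired slices, a learning rate held constant
for 100 epochs then decayed linearly to zero over the next 100 (the final
epoch runs at rate 0 under this convention), and a 50-image history buffer
per discriminator: below capacity fakes are stored and passed through; at
capacity each fake is swapped with probability 1/2 against a uniformly
drawn stored image.

## Design choices where the formulation is open

* **SSIM windowing.** Uniform 11&times;11 windows with *valid* positioning
  (no padding); the kernel type and padding are not pinned by the
  formulation, and the uniform/valid contract is the simplest one compatible
  with "mean over all regions". Note `C2 = 0.009` differs from the
  conventional `(0.03)^2 = 0.0009`; the package defaults to `0.009` and
  exposes the conventional value through `ssim_constants(c2 = 0.0009)`.
* **SSIM intensity scale.** Training-time SSIM is computed on slices
  rescaled to `[0, 1]`; the constants above are only meaningful on a fixed
  scale.
* **Flow direction semantics.** `f[n, k]` is the field that, applied to
  slice `n` by backward sampling (`warp()`), best reconstructs slice `k`;
  boundary slices contribute only their available one-sided term, unscaled.
* **Farneback hyperparameters** (none are pinned by the formulation):
  pyramid scale 0.5, 3 levels, box averaging window 15, 3 iterations per
  level, polynomial expansion half-width 5 with Gaussian applicability
  sigma 1.1; slice pairs are jointly rescaled to `[0, 255]` before
  estimation. The displacement iteration fetches the second expansion by
  bilinear sampling at the current (full, fractional) displacement so the
  `A d` compensation matches the fetch exactly; a rounded fetch paired with
  a full-displacement compensation overshoots systematically (this is
  observable on an exactly translated quadratic image, which the test suite
  checks).
* **Generator internals.** The residual translation generator follows the
  canonical 9-block design: 7&times;7 reflection-padded stem, two stride-2
  downsamplings, residual blocks at 4&times; the base width, two
  nearest-neighbour upsamplings each followed by a 3&times;3 convolution,
  and a 7&times;7 tanh head. Instance normalization is used throughout (the
  normalization layer is unspecified in the source formulation; this is the
  standard choice for this family). Input is linearly mapped from
  `[0, 65535]` to `[-1, 1]` and back on output.
* **Discriminator head.** The decision map of the final 1-channel
  convolution is passed through a sigmoid and spatially averaged to a single
  scalar per image in `[0, 1]`; a patch-map output (no averaging) is
  available via `discriminator_spec(patch_output = TRUE)` but off by
  default.
* **CT 16-bit mapping.** CT volumes are mapped with the fixed global range
  `[-1024, 1400]` HU rather than per-volume min-max, so one HU value always
  encodes to one 16-bit value across volumes and evaluation can denormalize
  consistently. MR uses per-volume min-max after truncation at the volume's
  99th in-body percentile (type-7 linear interpolation between order
  statistics; background voxels are excluded because they would dominate
  the percentile). Quantization rounds half-to-even; the round trip is
  exact to within half a quantization step (~0.018 HU for CT).
* **PSNR modes.** The literal formula divides `MAX_I = 65535` by the MSE,
  which cannot produce ~57 dB at ~40 HU MAE; the conventional definition
  divides by the RMSE. Both are implemented (`psnr(..., mode = "paper")`
  and `mode = "standard"`); `"standard"` is the default. Neither mode is
  asserted to reproduce any particular benchmark value.
* **Aggregation.** Across-volume mean &plusmn; SD uses the population SD.
* **Discriminator update cadence.** Both discriminators are updated every
  step (their net loss is the two-modality average, which couples them).

## The phantom generator

Real paired pelvis data cannot ship with the package, so `generate_phantom()`
builds co-registered pseudo-CT/pseudo-MR pairs: an elliptical body over air
(&minus;1000 HU), two femoral-head-like bone discs (~800-1200 HU), a
bladder-like ellipse (~0-30 HU), a rectum-like ellipse with an air core
(~&minus;900 HU), textured soft tissue (~20-80 HU), and Gaussian noise
(10 HU CT / 8 units MR by default). The MR is a per-tissue monotone
remapping with inverted bone contrast, its own texture, a smooth
multiplicative bias field, and sparse bright outliers that give the
99th-percentile truncation something to remove.

Three constructional details matter for the flow pipeline:

* the body centre follows a smooth random walk across slices (default max
  step 1 px), *reflected* at &plusmn;3 px so the walk never flattens;
  semi-axes follow their own small random walk (anatomy is not rigid);
* textures are analytic band-limited cosine fields evaluated at the drifted
  coordinates, so a drifting structure carries its texture exactly — no
  resampling smoothing enters the construction;
* tissue boundaries are composited with a ~1.5 px partial-volume
  transition. Hard re-rasterized edges make sub-pixel drift unrepresentable
  on the pixel grid — even warping by the *true* drift then increases the
  neighbour residual — whereas soft edges (like real CT partial-volume
  edges) keep the interslice change flow-recoverable. Binary masks are the
  0.5 threshold of the coverage.

What the phantom does **not** emulate: real anatomy (organ shapes are
ellipses), scanner physics (no TR/TE dependence, no MR distortion or
susceptibility artifacts), interscan differences such as moving air pockets,
out-of-plane motion, and registration error between MR and CT (phantom pairs
are perfectly aligned). A passing pipeline on phantoms therefore
demonstrates the machinery — losses, gradients, flow, schedules, HU
round-trips — not clinical image quality.

## Scaled-down study sizes

The reference configuration (256&times;256 slices, `ngf = ndf = 64`, 9
residual blocks, 200 epochs) is what the defaults encode, but CPU test runs
use deliberately small problems: a 4-patient 64&times;64&times;12 cohort
with sites 1/2/2/3 (so the site split yields 3 training and 1 test volume),
networks at `ngf = ndf = 3` with 2 residual blocks, batch 4, 200 optimizer
steps, 3 seeds. At this size one optimizer step costs a few tenths of a
second on one CPU, which keeps the whole behavioural suite within a normal
`R CMD check`-style budget. The behavioural claims checked at this scale
are directional — the net generator loss decreases, brief training beats an
untrained generator on body MAE, and the flow-constrained variants keep
adjacent-slice flow residuals at or below the plain cycle model's — not
reproductions of full-scale results.

## Numerical notes

* The network engine is a compact layer framework with hand-derived
  backpropagation over im2col convolutions (RcppArmadillo); every layer and
  both full architectures are finite-difference-checked in the tests.
* Instance normalization uses biased variance with `eps = 1e-5`.
* The SSIM training gradient is analytic (a per-window decomposition into a
  constant, an `x`-proportional and a `y`-proportional coefficient, each
  scattered back over its window with integral images) and is
  finite-difference-checked.
* `warp()` clamps sample coordinates (border replication) and is bit-exact
  under zero flow; its adjoint scatters bilinear weights and is
  finite-difference-checked.
* Degenerate inputs fail loudly: constant MR volumes (no percentile),
  equal normalization bounds, empty masks, volumes with fewer than 5 slices
  (trimming would consume them), flow on fewer than 2 slices.
* The Farneback local systems are regularized by `1e-4 * mean(trace(G))`
  before inversion so pure-noise and constant regions stay finite.
* Bicubic resizing uses the Keys kernel (`a = -0.5`) with half-pixel-centre
  coordinates and edge clamping; rows of the weight matrix sum to 1, so
  constant slices are preserved exactly. Masks are resized
  nearest-neighbour to stay binary.

## Known limitations

* CPU-only; no GPU path. Full-scale (256&times;256, width-64) training is
  supported by the code but takes far longer than any test budget — the
  engine exists to make the method testable and auditable, not fast.
* 2D slice models with a 2D flow constraint; no volumetric (3D)
  convolutions or 3D flow.
* The discriminator scalar head averages the patch map; a learned global
  head is not provided.
* `estimate_body_mask()` (Otsu + largest component, via EBImage) is a
  convenience for unmasked data, not a validated segmentation method.
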