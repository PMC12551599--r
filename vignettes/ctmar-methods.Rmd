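---
title: "Metal artifact reduction with latent-diffusion priors: models, parameters and design choices"
author: "ctmar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metal artifact reduction with latent-diffusion priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Metal implants corrupt CT reconstructions through beam hardening, photon
starvation, scatter and nonlinear partial-volume effects: rays that cross
metal carry inconsistent line integrals, and filtered backprojection (FBP)
turns that inconsistency into dark bands between metal objects and streaks
radiating from them. Projection-domain metal artifact reduction (MAR)
replaces the *metal trace* — the sinogram entries whose rays intersect
metal — with plausible values before reconstruction.

The workflow implemented here chains:

1. **FBP** of the measured fan-beam sinogram (the *corrupted* image).
2. A **conditional latent diffusion model (LDM)** that synthesizes an
   artifact-reduced *prior image* from the corrupted image: a
   vector-quantized autoencoder (VQ-VAE) maps slices to a compact latent
   grid, and a conditional denoising diffusion model, guided at every step
   by the corrupted image's latent, generates a clean-image latent that is
   decoded back.
3. A learned **metal segmentation** network (replacing image-domain
   thresholding) whose mask is forward projected to the trace.
4. **Normalized MAR (NMAR)**: divide the measured sinogram by the forward
   projection of the prior, inpaint the trace in the normalized domain,
   multiply back, and reconstruct.
5. Optional **secondary artifact correction** that reuses the trained LDM
   to refine the NMAR result from a partially noised latent.

Classical **LIMAR** (per-view linear interpolation of the trace) and
threshold-prior NMAR are implemented as baselines, together with an
evaluation harness (RMSE, PSNR, SSIM, flat-ROI standard deviation) and an
ablation runner.

# The forward model and simulator

No public paired dental data exist, so every stage is validated on a
physics-based simulator that produces paired clean/corrupted slices.

**Geometry.** All learned parts of the workflow are two-dimensional and are
applied slice by slice, so the package uses a 2D fan-beam geometry with a
flat (equidistant) detector rather than a 3D cone beam. The default desk
scale is a 64 × 64 grid at 3 mm pixels, source-to-isocenter 400 mm,
source-to-detector 800 mm, 144 detector elements at 4 mm pitch, 180 views
over 360°. A lateral detector `offset` parameter exists for half-fan
configurations but only full-fan scans are exercised by the tests; how
truncated offset-detector data interact with NMAR normalization is out of
scope. Line integrals are evaluated by Joseph-style sampling with bilinear
interpolation at steps of half a pixel; the unfiltered backprojector is the
exact adjoint of the forward projector. FBP uses cosine weighting, the
standard discrete ramp kernel (optionally cosine-apodized) after
zero-padding to the next power of two, pixel-driven backprojection with
inverse-square distance weighting, and Parker-style weights when the arc is
short of 360°.

**Phantom.** A dental-arch section: a PMMA-like soft-tissue ellipse
(82 × 74 mm semi-axes), eight bone-equivalent (Teflon-surrogate) teeth on a
52 mm arch, a throat air pocket, and metal inserts (cylinders or screw
shapes) seated inside teeth. A seeded low-frequency texture field perturbs
the soft-tissue attenuation (±6%), emulating the clay-mixture variability a
physical phantom would show between scans. The *clean* member of a pair
replaces metal labels by bone and is reconstructed from a monoenergetic,
noise-free acquisition; the *corrupted* member is the polychromatic, noisy
acquisition of the same realization with metal.

**Physics.** Attenuation follows a two-term model per material
(photoelectric ∝ E⁻³ plus Compton ∝ Klein–Nishina), tabulated on a
25–95 keV grid; the spectrum is a 12-bin Kramers-shaped 95 kVp tube
spectrum with mild low-energy filtration. Detected intensity per ray is
`sum_E w(E) exp(-∫ mu(E))`; Poisson noise is applied at 8 000 blank photons
per ray and counts are floored at one photon before the log (photon
starvation). Scatter is not simulated (clinical scanners pre-correct it).

**Artifact severity (a deliberate calibration).** With these choices the
simulator is asked to reproduce the artifact-severity *regime* of a
physical dental phantom study, where the corrupted image is roughly 50%
worse than LIMAR in RMSE and an oracle-prior NMAR is ~3× better. Titanium's
textbook attenuation alone, without scatter and nonlinear partial-volume
effects, produces artifacts too mild for that regime at this grid scale, so
the metal insert uses a denser dental-alloy surrogate (photoelectric 0.30,
Compton 0.06 mm⁻¹ at 60 keV) and three 5 mm inserts. Only the *ordering*
and energy dependence of the material table matter for the method; the
table is not dosimetrically accurate. The clean reference is reconstructed
at 54 keV, the effective energy of the default spectrum, so clean and
corrupted share the same soft-tissue baseline and local dark bands are not
masked by a global beam-hardening offset.

What the simulator does *not* emulate: scatter tails, detector lag and
gain nonuniformity, 3D cone-angle inconsistency, anatomical variability of
real patients, and clinically diverse metal shapes and materials. Tests
passing on this simulator demonstrate correctness of the algorithms and the
expected *directional* behaviour of the pipeline, not clinical performance.

# Learned components

All networks are small convolutional models implemented in the package
(im2col-based conv kernels in C++, BLAS matrix products, Adam), sized for
single-CPU training in seconds to minutes.

**VQ-VAE codec.** Encoder: two stride-2 convolutions (24, 48 channels) and
a projection to a 16 × 16 × 4 latent grid (downsample factor 4, embedding
dimension 4); nearest-neighbour quantization against 256 code vectors;
mirrored decoder. Intensities are windowed from [0, 0.05] mm⁻¹ to [−1, 1]
(values above the window — metal — extend to a clamp of 3). The training
loss is the four-term composite: reconstruction MSE, codebook term
`||sg[E(x)] − z_q||²`, commitment term `β||E(x) − sg[z_q]||²` with
β = 0.25, and a perceptual feature distance with weight λₚ = 0.01. The
perceptual extractor is a *fixed, seeded random* two-layer convolutional
stack with unit channel weights: it preserves the loss's structure and all
of its identities (zero iff the inputs agree) without requiring pretrained
weights, which are unavailable offline. Stop-gradients are implemented
analytically: the codebook term moves only code vectors, the commitment
term only the encoder, and the reconstruction gradient reaches the encoder
through the straight-through copy; the routing is verified against finite
differences in the tests. Codes whose decayed usage falls below a
threshold are re-anchored to k-means centres of recent encoder outputs
(online codebook clustering); an optional contrastive latent-shaping term
is not implemented beyond this mechanism, since no weighting for it is
established.

**Conditional latent diffusion.** Linear variance schedule β_t from 1e-4
to 2e-2 over T = 200 steps (a desk-scale compression of the conventional
1000-step protocol; T is configurable). The forward marginal is the closed
form `x_t = sqrt(ab_t) x0 + sqrt(1 − ab_t) ε` with `ab_0 = 1`. The noise
predictor is a four-layer conv net on the channel-concatenated (noisy
latent, condition latent) with a cosine time embedding entering as a
learned per-channel bias; training minimizes `||ε − ε̂(x_t, y, t)||²` with
t uniform. Sampling is deterministic DDIM (η = 0) over 5 uniformly spaced
steps, with the corrupted-image latent supplied as a *constant* condition
at every step. The changing-condition ablation
`((T − t)·Corrupted − t)/T` — fully corrupted-guided at t = 0, pure −1 at
t = T — is implemented as stated; its step index t is taken to increase
from the start of generation (t = 0) to the end (t = T), and the direction
is exposed should the opposite reading be wanted. Latents are normalized
per channel (mean/sd over the training set) before diffusion; the
statistics are part of the checkpoint.

**Metal segmentation.** A compact two-scale U-net (12 base channels, skip
concatenation, sigmoid output) trained with Dice + BCE on a synthesized
dataset: artifact maps (corrupted − clean) from phantom pairs are rotated
by seeded random angles and overlaid onto metal-free slices, with the
identically rotated metal mask as label. Training uses 600 samples for 10
epochs on seeded random 32 × 32 crops biased toward metal-containing
windows (the network is fully convolutional, so inference runs on full
slices); held-out Dice exceeds 0.9 and metal-free slices yield empty
masks. An adaptive-threshold + morphology pseudo-labelling route
(`pseudoLabel`) exists for slices without ground truth; its parameters are
config-exposed defaults, not calibrated to any scanner. Inference masks
drop connected components below 4 pixels.

# NMAR details and numerical choices

- Trace: forward projection of the binary mask, thresholded at 1e-9,
  dilated by 1 detector pixel to absorb projector edge effects.
- Prior projection clamp: `eps = 1e-4 × median(positive prior projection)`;
  division and re-multiplication are exactly inverse off the trace, and the
  output is copied bit-for-bit from the input outside the trace.
- Trace inpainting in the normalized domain: harmonic by default (Laplace
  equation on the view × detector grid, SOR iteration, Dirichlet data from
  untraced neighbours, Neumann at grid edges; initialisation by per-row
  linear interpolation), or per-row linear interpolation. Harmonic
  completion is smooth across views, which reduces view-to-view jitter of
  the completed trace.
- LIMAR boundary convention: a traced run touching the detector edge is
  filled by constant extension of its single available neighbour; a fully
  traced view falls back to the nearest untraced view with a warning.
- Metal handling in the final image: the original (FBP) metal pixels are
  reinserted by default; evaluation reports RMSE both with metal excluded
  (primary, since the clean reference replaces metal by bone) and included.
- The evaluation ROI ("between the dental arch") is derived automatically
  as the largest disc centred at the metal-insert centroid that fits inside
  the soft-tissue label region.
- PSNR uses the normalization window width (0.05 mm⁻¹) as its reference
  range; SSIM uses a Gaussian window (σ = 1.5) and the standard constants
  with the same dynamic range.

# Desk-scale study sizes

The test suite and the acceptance script train and evaluate at fixed,
deliberately small sizes chosen as this package's study conditions: a
20-pair simulation suite for method orderings; 10 pairs (20 slices) for
codec/LDM training with 4 held-out pairs; 600 synthesized samples for the
segmentation network; 45 codec epochs, 4000 diffusion steps at batch 8.
These sizes give stable orderings and held-out metrics (codec ≈ 26 dB,
segmentation Dice ≈ 0.93, LDM prior RMSE below the corrupted input on every
held-out pair) while keeping any single run in minutes on one CPU.

# Known limitations

- **Secondary artifact correction does not improve RMSE at this scale.**
  The refinement necessarily decodes through the codec, whose
  reconstruction floor (~0.0024 mm⁻¹ at 26 dB) exceeds the error of the
  NMAR result it refines (~0.0022 mm⁻¹); and the small noise predictor's
  residual error injects more energy than the interpolation streaks it
  removes. The operation is implemented and tested for its contracts
  (exact codec round trip in the zero-start limit, determinism, both
  partial and full-trajectory modes), it does reduce flat-ROI standard
  deviation relative to the corrupted input and threshold-prior NMAR, but
  the configuration in which it also preserves RMSE within a few percent
  requires a higher-fidelity codec than the desk scale affords. It is
  therefore off by default in the pipeline (`secondary = FALSE`).
- The latent downsampling factor is a configuration choice (it trades
  codec fidelity against diffusion cost); the package default is 4.
- Parker weighting for short scans is implemented but the default test
  configurations use full 360° scans; short-scan cone-beam effects,
  offset-detector truncation, scatter and real DICOM ingestion are out of
  scope.
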