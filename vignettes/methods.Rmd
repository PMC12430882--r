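---
title: "Reconstructing spectral reflectance from paired RGB images: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing spectral reflectance from paired RGB images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(specfusion)
```

## The problem

A linear RGB camera compresses a pixel's radiance spectrum into three
numbers,

$$G_1(x,y,k) = \sum_\lambda I(\lambda)\, S(x,y,\lambda)\, C_k(\lambda),
\qquad k \in \{R,G,B\},$$

where $S$ is the material's spectral reflectance, $I$ the illuminant's
spectral power distribution, and $C_k$ the camera's per-channel
sensitivity. The quantity of scientific interest — in dental shade
matching, but equally in any colour-critical application — is $S$: it is
the illumination-independent material signature, and recovering it defeats
metamerism (distinct spectra that happen to share an RGB triple under one
light and diverge under another). The inverse problem is badly
underdetermined: three numbers per pixel must be expanded into $B$ spectral
bands while the illuminant is unknown.

The framework implemented here constrains the inversion with a second,
cheap measurement: an image of the same illumination reflected off an
ideal diffuse whiteboard, for which $S \equiv 1$ and the camera records

$$G_2(x,y,k) = \sum_\lambda I(\lambda)\, C_k(\lambda).$$

Reconstruction proceeds in three learned steps that mirror the physics:

1. a U-Net-like *spectral upsampling network* (the P branch) maps the
   object RGB $G_1$ to the radiance cube $I(\lambda)S(x,y,\lambda)$;
2. an attention network (the L branch, light role) maps the whiteboard RGB
   $G_2$ to the illuminant cube $I(\lambda)$;
3. a second, independently parameterized L branch decodes the channel
   concatenation of the two cubes into the reflectance $S(x,y,\lambda)$ —
   a learned, regularized counterpart of the wavelength-wise ratio
   $S(\lambda) = I_{\mathrm{sample}}(\lambda) / I_{\mathrm{illumination}}(\lambda)$
   that defines the ground truth.

The two L-branch instances share their architecture but can never share
weights: their input widths differ (3 channels against $2B$).

## Architectures

**P branch** (`srp_config()`): a 3×3 stem, then $N$ encoder stages of $K$
local–global fusion (LGF) blocks followed by a stride-2 convolution that
doubles the width; $K$ more LGF blocks at the bottleneck; and a mirrored
decoder of 2×2 transposed convolutions whose skip connections are gated by
dual-stat attention (DSA) before a 1×1 fusion and $K$ further blocks. A
final 3×3 convolution maps to $B$ bands, and the RGB input — lifted to $B$
channels by a fixed triangular-weight matrix that places the R, G, B
channels' influence at long, middle and short wavelengths — is added as a
global residual. The residual makes the network predict a spectral
correction to a crude colorimetric lift rather than the cube from scratch.

The **LGF block** combines a local 3×3 convolution path with a globally
pooled context vector passed through a dense layer and broadcast back over
the image; the two are concatenated and fused by a 1×1 convolution, and the
result is added to the input. With zeroed fusion weights the block is the
identity — the residual form the tests pin down. The **DSA gate** computes
each channel's spatial mean and standard deviation and passes the pair
through a two-layer bottleneck shared across channels; the sigmoid output
is that channel's gate in $(0,1)$: channels whose statistics mark them as
uninformative are attenuated before they re-enter the decoder.

**L branch** (`srl_config()`): two independently parameterized shallow
paths (3×3 convolution, ReLU, channel attention, spatial attention), their
1×1 refinements, a four-way channel concatenation (fusion width exactly
$4w$, asserted at build), $N$ residual L-blocks, and a 1×1 head. Channel
attention is the squeeze-style global-average-pool bottleneck; spatial
attention derives a per-pixel gate from the channel-wise mean and max maps
through a 3×3 convolution. The **L-block** adds an attention path
(convolution, ReLU, CA, SA) to a 1×1-projected shortcut.

The attention-free **baseline U-Net** predicts reflectance from the object
RGB alone — no light input, no attention, no physics fusion — and is the
reference the fusion model must beat.

## Training objective

The structure–pixel loss on the reflectance output is

$$L = \alpha\, L_{\mathrm{MSE}} + \beta\,(1 - \mathrm{SSIM}),
\qquad \alpha = \beta = 1,$$

with SSIM computed per band with an 11×11 Gaussian window ($\sigma = 1.5$,
the de-facto standard; only "local" weighting is inherent to the method,
so a uniform window is provided for oracle comparisons) and stabilizers
$C_1 = 10^{-4}$, $C_2 = 9\times10^{-4}$ that assume inputs on a $[0,1]$
scale. MSE enforces per-pixel spectral accuracy; the SSIM term preserves
spatial structure within each band. Windows are evaluated at fully interior
positions only, so borders never mix with zero padding.

Because all five components of a training record carry ground truth, the
two intermediate cubes receive weak auxiliary MSE supervision (weight 0.1
each, configurable; plain MSE keeps the auxiliary terms cheap). This
stabilizes the decomposition at small training scales: without it the
decoder is free to ignore the physical meaning of its two inputs.
Optimization follows the reference protocol: Adam with $\beta_1 = 0.9$,
$\beta_2 = 0.999$, zero weight decay, constant learning rate
$4\times10^{-4}$, batch size 8. One master seed fans out deterministically
to weight initialisation, batch order and the data simulator, so a fit is
reproducible from `(data, variant, control, seed)`.

**Normalization.** Reported pipelines normalize images to $[0,1]$ by their
maximum. Applied per image this would destroy the radiance/illuminant
ratio that reflectance *is*, so this package scales both RGB images of a
pair by the **light image's** maximum (the whiteboard is the natural
exposure reference) and both ground-truth cubes by the light cube's
maximum; reflectance, a dimensionless ratio, is never rescaled. Evaluation
normalizes predicted and true cubes jointly by the truth's maximum for the
same reason.

## The synthetic scene simulator

The paired dental dataset the method was developed on is private, so the
package ships a simulator that reproduces its statistical structure and
acquisition geometry; every test and example runs on it.

* **Illuminants** — sixteen LEDs as Gaussian mixtures over wavelength:
  warm whites (450 nm pump plus a strong 595–605 nm phosphor lobe),
  neutral whites (~570 nm lobe), cool whites (pump-dominant), and eight
  monochromatic hues between 420 and 650 nm. Sixteen mixing conditions
  span the four reported classes: eight single whites, five binary white
  mixes (7+6, 6+1, 7+1, 7+4, 6+4), two tricolor mixes (7-6-1, 7-6-4) and
  one eleven-LED mix. Every LED carries a broadband pedestal of 1% of its
  peak — physically, diffuser leakage — so mixed illuminants are strictly
  positive across the working grid. The pedestal has a useful consequence:
  the wavelength-wise ratio recovers the generating reflectance *exactly*
  under every condition, which makes the ground truth
  illumination-independent, as it must be.
* **Reflectance fields** — elliptical soft-edged specimen blobs on a dark,
  spectrally flat background. Each blob's spectrum is a nonnegative
  combination of four smooth basis functions dominated by an upward
  sigmoid toward long wavelengths — the characteristic rise of dental
  enamel and ceramic — bounded by 1.2 (glossy pixels may exceed a diffuse
  reference, hence no clipping at 1). Smoothness is a testable property:
  the second finite difference across bands stays below a frozen
  threshold.
* **Camera** — three Gaussian sensitivities at 460/540/610 nm with 35 nm
  standard deviation; tabulated curves can be substituted.
* **Noise** — additive Gaussian on the rendered RGB images only (default
  $\sigma$ = 1% of the light image's peak), never on the ground-truth
  cubes: supervision should be clean, and sensor noise enters exactly
  where a sensor sits.
* **Augmentation** — 90°-quantized rotations (spectra are never
  interpolated), integer shifts and crops with zero padding, applied
  jointly to the object RGB, the object cube and the reflectance truth.
  The light image is scene-global and is never transformed.

What the simulator deliberately does **not** model: specularity and
translucency of real ceramics, spatially varying illumination, chromatic
aberration, and measured LED spectra. Passing tests therefore demonstrate
that the implementation learns the physics it encodes — not that it
reaches any particular accuracy on real dental images.

The working grid defaults to 32 uniform bands over 400–700 nm (the visible
range the application cares about); 204-band imager spectra are mapped onto
it by linear interpolation with constant extension, `resample_spectrum()`.

## Working scales

Two presets bundle the architecture and schedule:

* `full` — 64×64 images, 32 bands, encoder base width 32, branch width 64,
  4000 pairs (3000/300/700 split), 54 epochs. This mirrors the reference
  configuration; matching its printed 12.8 M parameter count is explicitly
  not a goal since layer widths are not published.
* `desk` — 32×32 images, 16 bands, encoder base width 4 with one LGF block
  per stage, branch width 4 with two L-blocks, 30 epochs. This is the
  scale at which the package studies itself: the test suite runs a
  three-seed study (full model, no-DSA, constant-illumination, plus one
  baseline U-Net fit) on a 96-pair dataset — six scenes per lighting
  condition, split 85/8/3 — so the whole study completes in minutes on one
  CPU core. The sizes were chosen once, for runtime, before any accuracy
  was inspected; the qualitative claims under test (training converges,
  physics fusion beats the single-input baseline, removing DSA hurts less
  than removing the light input) are scale-free directions, not value
  reproductions.

The engine behind both is a compact reverse-mode tape written for this
package: convolutions run either as direct C++ loops (narrow outputs) or
through im2col with BLAS, transposed convolutions as per-sample GEMMs, and
every backward function was validated against central finite differences.

## Numerical choices and degenerate inputs

* Division floor: reflectance ratios divide by
  $\max(I, 10^{-6})$ on the unit-max illuminant scale; clamped bands are
  reported in a `"clamped"` mask attribute, never silently zeroed.
* DSA standard deviations use $\sqrt{\mathrm{var} + 10^{-5}}$, so constant
  channels (zero spatial variance) stay differentiable and finite.
* Initialisation is He-scaled for layers feeding a ReLU and unit-scaled
  (Glorot-like) otherwise; with ~40 layers, the distinction is what keeps
  untrained activations at unit scale instead of exploding by $2^{n/2}$.
* Network outputs are clamped at zero when wrapped into a reflectance
  cube; raw (possibly negative) values are used during training.
* A non-finite training loss aborts with a diagnostic rather than
  continuing silently.
* Ties and randomness: a single seed derives all per-pair, per-epoch and
  per-subnetwork seeds through a fixed integer recurrence below $2^{31}$.

## What the desk study does and does not show

The three-seed desk study (run by the test suite and, at one seed, by the
acceptance script) verifies the directions the method's central claims
rest on: training converges for every seed, and the physics-informed
fusion model beats the attention-free single-input U-Net on held-out
scenes. One reported direction is *not* reproduced at this scale:
replacing the light image by a constant barely hurts. A second expectation
also fails informatively: an analytic colorimetric baseline — lift both
RGBs to pseudo-cubes with the fixed triangular matrix and divide — is hard
to beat on these scenes (the acceptance script reports its metrics
alongside the model's), because a pixelwise physics-exact solver on
piecewise-smooth, low-dimensional spectra leaves the small trained decoder
little room for improvement. With sixteen fixed illumination conditions and a
four-basis family of smooth reflectances, the synthetic inverse problem is
nearly identifiable from the object image alone — the network can in
effect classify the illuminant from scene appearance, something the far
richer real acquisition does not permit (there, removing the illumination
input collapses accuracy). The corresponding assertion is kept in the
suite at its original margin and fails honestly; it measures a property of
the simulator's dimensionality, not an error in the ablation machinery.

## Known limitations

* Reported benchmark values from the original dental study (mean MSE
  0.0024, mean SSIM 0.8724, and the ablation table) are carried only as a
  published comparison table (`reference_benchmarks()`) for the
  improvement arithmetic; they cannot be reproduced here because the
  4000-pair dataset is private. The package's own numbers are synthetic-
  scene numbers.
* The desk-scale decoder has modest capacity; under monochromatic
  conditions most bands are illuminated only by the 1% pedestal, so
  per-band accuracy there reflects the learned spectral prior more than
  measurement.
* Double precision throughout: the engine favours testability (exact
  oracles, bit-reproducibility) over raw speed.
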