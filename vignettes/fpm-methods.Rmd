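---
title: "Model and methods behind fpmicro"
author: "fpmicro authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind fpmicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The imaging model

Fourier ptychographic microscopy (FPM) captures one low-resolution (LR)
intensity image per LED of a programmable array and recovers a
high-resolution (HR) *complex* image — intensity and quantitative phase —
by stitching the illumination-shifted pupil passbands in the frequency
domain.  `fpmicro` implements the forward physics of that acquisition and
inverts it by gradient descent.

The sample is a thin complex transmittance on the HR grid,

$$o(\mathbf r) = \exp\!\big(i\,\varphi(\mathbf r) - \mu(\mathbf r)\big),$$

with phase $\varphi$ (radians, the quantitative-phase signal) and
absorption exponent $\mu \ge 0$, so $|o| = e^{-\mu} \in (0,1]$
(`ComplexObject`).  An LED at lateral offset $(d_x, d_y)$ and stand-off
$h$ illuminates the sample with a tilted plane wave whose spectral shift
is

$$\mathbf k_m = \frac{1}{\lambda}\left(\frac{d_x}{\sqrt{d_x^2+d_y^2+h^2}},\;
\frac{d_y}{\sqrt{d_x^2+d_y^2+h^2}}\right),$$

(`ledWavevectors()`; LEDs ordered by a deterministic center-outward
spiral so index 1 is on-axis).  The capture under LED $m_i$ with defocus
$z$ is

$$I_i = \gamma_i \left| \mathcal F^{-1}\!\big[\, o(\mathbf k - \mathbf k_{m_i})
\, P(\mathbf k)\, H(\mathbf k, z) \,\big] \right|^2,$$

where $P$ is the objective's coherent transfer function — an NA-limited
disk carrying a Noll-indexed Zernike phase
$P = \mathrm{disk}\cdot\exp(i \sum_j c_j Z_j)$ — $H$ is the
angular-spectrum defocus kernel

$$H(\mathbf k, z) = \exp\!\Big(i \tfrac{2\pi}{\lambda} z
\sqrt{1 - (\lambda k_x)^2 - (\lambda k_y)^2}\Big),$$

and $\gamma_i > 0$ absorbs LED-to-LED brightness differences.  Spectra
are DC-centered and transforms unitary; the shift $\mathbf k_m$ is
applied as the nearest-integer pixel offset of the LR-sized spectrum
window (no sub-pixel interpolation — standard FPM practice, and it makes
the simulator and reconstructor share one discretisation exactly).

Two discretisation choices deserve note:

* **Evanescent frequencies.**  Where $(\lambda k)^2 > 1$ the kernel is
  the real decay $\exp(-\tfrac{2\pi}{\lambda}|z|\sqrt{(\lambda k)^2-1})$
  rather than a hard zero.  At any realistic defocus this is
  indistinguishable from zero, but it keeps $H$ continuous at $z = 0$,
  which the two-plane simulator's zero-separation limit requires, and
  uses $|z|$ so that back-propagation never amplifies.  The pupil disk
  (NA < 1) excludes the evanescent region from every imaging step
  anyway.
* **Grids.**  Both grids are square and even-sided, span the same field
  of view, and therefore share one frequency step; the HR side is
  `hrUpsample` times the LR side, and the object-plane LR pixel is
  `cameraPixel / magnification` (0.65 um for the reference 10x / 6.5 um
  geometry).

## Joint reconstruction as gradient descent

Reconstruction minimises the mean per-pixel data misfit over the $N$
captures,

$$\varepsilon = \frac{1}{N}\sum_{i=1}^{N}
\mathrm{mean}\big(\,\lvert I_i^{\mathrm{pred}} - I_i^{\mathrm{obs}}\rvert\,\big),$$

jointly over four parameter groups: the HR object spectrum (complex,
optimised directly), the pupil Zernike coefficients, the scalar defocus
$z$, and the per-capture intensity factors parameterised as
$\gamma_i = e^{g_i}$ so they stay positive.  The L1 misfit is the
default; a squared (L2) variant is retained as an option.  No autodiff
framework is used: the gradients are derived analytically by Wirtinger
calculus through the crop–multiply–transform–modulus chain and are
verified against finite differences in the test suite.  Updates use a
hand-written Adam optimiser over mini-batches of LEDs, shuffled each
epoch under the optimiser seed, so every run is bit-reproducible.

Initialisation follows standard practice: the amplitude starts from the
square root of the central-LED capture replicated onto the HR grid with
zero phase, $z = 0$, Zernike coefficients $(1, 0, \ldots, 0)$ (a pure
piston, i.e. an unaberrated pupil), and $\gamma_i \equiv 1$.

### Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `lossKind` | `"L1"` | robust data misfit; `"L2"` optional |
| `epochs` | 200 | fixed budget, no early stopping — the simplest reproducible contract |
| `batchSize` | 13 | one LED ring's worth per step; 13 batches per epoch for the 13x13 array |
| lr `spectrum` | 1e-2 | Adam step for the complex spectrum (real and imaginary parts treated as separate coordinates) |
| lr `pupil` | 1e-3 | radians per step on Zernike coefficients |
| lr `z` | 0.1 | micrometres per step |
| lr `gamma` | 3e-3 | log-units per step |
| `lrSchedule` | `"cosine"` | anneal to zero over the budget |
| `seed` | 0 | batch shuffling only |

The cosine schedule matters on noiseless data: constant-rate Adam leaves
a stochastic-step jitter floor around $10^{-4}$ in the L1 loss, which
completely masks the signal of the dimmest high-angle captures (their
whole frames are of order $10^{-4}$).  Annealing lets the fit settle
orders of magnitude lower, making those frames' intensity factors
identifiable.  The $\gamma$ group additionally uses a shorter Adam
second-moment memory ($\beta_2 = 0.99$): its early gradients are large
and noisy while the spectrum is still wrong, and the default long memory
would suppress the genuine late-run signal.

These step sizes were chosen by convergence experiments on synthetic
stacks; they are declared package defaults, all overridable through
`optimizerSpec()`.  Known limitation: for some phantom realisations,
isolated purely-darkfield LEDs retain a few percent error in
$\hat\gamma$ at the 200-epoch default (the per-frame scale trades off
slowly against frame-private high-frequency spectrum content); doubling
the epochs removes it.

### Gauge freedoms

Intensity measurements fix the object only up to a global phase (piston)
and a global intensity scale shared between the spectrum and the
$\gamma$ vector; the pupil piston coefficient is likewise a pure gauge.
All quality metrics therefore gauge-fix first: `amplitudeRmse()` applies
a least-squares scalar fit, `phaseCorrelation()` removes the mean phase,
and $\gamma$ comparisons normalise the central LED's factor to 1.
`extractObject()` removes the circular-mean piston from the phase map
and reports how many pixels needed clipping when converting amplitude
back to a nonnegative absorption exponent.  A related near-degeneracy —
the Zernike defocus term versus the $z$ parameter — is broken only when
one of the two is frozen; pupil-recovery experiments therefore pin $z$.

## Digital refocusing

The defocus enters the model analytically through $H(\mathbf k, z)$, so
$z$ can be recovered like any other parameter (`refocus()`).  Two modes:

* `sweep`: short reconstructions with $z$ frozen at each candidate of a
  grid; the focus score is the final reconstruction loss (staying inside
  the model-fitting framework; no image-sharpness heuristic), the argmin
  wins, ties break toward smaller $|z|$, and an argmin on the range
  boundary raises a flag.
* `joint_opt`: a full reconstruction with $z$ free.  Because intensity
  data admit a near-degenerate conjugate-twin explanation at the
  mirrored defocus, plain descent from $z = 0$ can be captured by the
  wrong basin beyond roughly $\pm 20$ um; the joint mode therefore
  warm-starts $z$ from a cheap 11-point frozen-$z$ coarse sweep and then
  lets it float.  Recovered defocus is accurate to well under a
  micrometre across $\pm 30$ um in the validation suite.

## Occluder suppression

Slides carry markers, dust and stains on surfaces axially separated from
the tissue.  The package models this as a two-plane scene: the tilted
illumination crosses the tissue, propagates by the plane separation with
the HR angular-spectrum kernel, is modulated by the occluder, and is
imaged through the pupil (`simulateTwoPlaneStack()`).  With a
transparent occluder this reduces *exactly* to the single-plane
simulator, and as the separation goes to zero it reduces to the product
of the two transmittances — both limits are tested, along with a
direct-sum propagation oracle.

`suppressOccluder()` is simply the reconstruction with $z$ frozen at the
chosen focal plane: content of that plane is rendered sharply while
content of other planes is inconsistent with the applied kernel across
illumination angles and blurs into a low-contrast background.  The
validation scenario acquires the stack focused at the marker plane (as
when marks on the slide surface visibly obscure the tissue) and
digitally refocuses to the tissue plane 150 um below; the masked RMSE
against the tissue truth drops to about 0.4 of the raw central-LED
frame's.  Scale caveat: at the desk-scale fields simulated here (10–20
um across), a 150 um-defocused marker blurs over the *entire* field —
wrap-around haze rather than a local shadow — so suppression ratios are
roughly flat in the separation, unlike the mm-scale fields of a real
camera where the blur stays local.

## RGB and phase outputs

Three single-wavelength reconstructions (623 / 523 / 470 nm, each with
its own illumination set and pupil) are stacked along the channel
dimension in that order by `assembleRgb()`, normalised per channel by a
recorded 99th percentile (robust to hot pixels, reversible).
`phaseToDisplay()` linearly rescales a phase map for display with the
(min, max) recorded; the radian values themselves are never altered and
no unwrapping is attempted — the phantoms and the weak-to-moderate
modulation regime keep $\varphi$ within a wrapped range, and unwrapping
is a separate problem with its own failure modes.

## What the synthetic data emulate — and what they do not

`makePhantom()` generates test objects on the HR grid:

* `tissue` — smoothed random stroma plus high-absorption, high-phase
  nuclei disks with correlated $\mu$ and $\varphi$ (stain raises both),
  plus a sub-micron granularity component.  The granularity is
  deliberate realism: stained tissue is spectrally broadband, and it is
  this broadband floor that gives high-angle darkfield captures their
  signal; without it those frames are ~5 orders dimmer than brightfield
  and their intensity factors are unidentifiable.  Ranges
  $\mu, \varphi \in [0, 1.5]$ keep $|o| \ge 0.22$ and the phase
  unwrapped.
* `two_point` — two transparent points at a stated separation on an
  absorbing background, for resolution probing.
* `star`, `bars`, `uniform` — standard structured targets.
* `makeOccluder()` — opaque marker strokes ($\mu = 3$, ~95% amplitude
  attenuation) on a transparent plane.

The simulations are fully coherent, monochromatic, single-field,
noiseless by default (optional Poisson shot noise at a stated photon
budget plus Gaussian read noise), with a perfectly known LED geometry.
Real acquisitions add partial coherence (finite LED size), LED position
errors, sample-thickness variation across the field, vignetting and
sensor nonlinearity — none of which are modelled.  Passing the synthetic
suite therefore demonstrates the correctness of the model and the
optimiser, not robustness to every physical nuisance of a real
microscope.

### Resolution accounting

For the reference geometry (13x13 LEDs, 4 mm pitch — a common
commercial array spacing, as the pitch is not part of the published
hardware description — at 52 mm, NA 0.3, 523 nm) the illumination NA of
the corner LED is 0.547, so the coherent two-point limits are
$\lambda / (2\,\mathrm{NA}) = 0.87$ um for a single capture and
$\lambda / (2(\mathrm{NA} + \mathrm{NA_{ill}})) = 0.31$ um for the
synthetic aperture.  The validation suite probes 2.6 / 0.65 / 0.325 um
two-point pairs under an explicit operational criterion — the profile
between the peaks must dip at least 20% below the lower peak — and finds
0.65 um resolved only by the reconstruction, 2.6 um by both, 0.325 um by
neither.

## Problem sizes and determinism

The validation experiments use a 128x128 HR grid (32x32 captures,
`hrUpsample` 4) for object, $\gamma$ and occluder recovery, and 64x64
HR grids for the defocus and resolution suites — sizes at which a full
200-epoch joint reconstruction completes in well under a minute on one
CPU while exercising every parameter group at the reference 13x13
geometry.  Every stochastic element (phantom generation, noise draws,
batch shuffling) is seeded; identical configuration plus seed reproduces
every artifact bit for bit, which the suite asserts.

## On-disk formats

Capture stacks are multi-page TIFF (one LR frame per page, spiral LED
order) with 32-bit samples of `image / scale`, where `scale` is an
exact power of two recorded in a YAML sidecar along with the full
optical configuration (lengths in um except LED pitch and height in
mm), LED ordering name, defocus, $\gamma$ vector, seed and noise spec.
The TIFF library stores 32-bit samples as fixed point in $[0,1]$, so
round trips are faithful to about $2\times10^{-10}\cdot$`scale` — far
beyond the 16-bit dialect also accepted on read.  HR maps (intensity,
phase, absorption) use the same mechanism with an additional recorded
offset for signed data.  `runFpm()` writes a YAML run report (loss
history, $\hat z$, $\hat\gamma$, Zernike coefficients, optimiser echo,
seeds) so that any artifact is reproducible from its config and seed
alone.
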