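---
title: "Ring-array photoacoustic tomography in ringpact: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring-array photoacoustic tomography in ringpact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ringpact)
```

`ringpact` implements the computational chain of a full-ring photoacoustic
computed tomography (PACT) breast scanner — forward acoustics, image
reconstruction, vascular analysis, dynamic (heartbeat and breathing) analysis
and vessel-density tumor segmentation — together with the synthetic phantoms
needed to exercise every stage without patient data. This vignette explains
the models, their assumptions, the tunable parameters, and the design
decisions taken where the underlying processing chain is under-specified.

## The system being modeled

The modeled scanner is a 512-element full-ring ultrasonic array of 220 mm
diameter. Each element is a flat rectangle, 5 mm tall (elevational axis) at
1.35 mm pitch, with a 2.25 MHz centre frequency and about 95% one-way
fractional bandwidth, sampled at 40 MHz for 100 µs after each laser pulse.
A single pulse yields one 2D cross-sectional frame (10 Hz frame rate); a
volumetric image is acquired by scanning the ring elevationally.

## Forward model (`simulate_sinogram`)

A photoacoustic source is modeled as a uniform sphere of radius $a$: the
pressure at distance $r$ is the classical bipolar N-shaped wave
$p(r,t) = A\,(r - ct)/(2r)$ for $|r - ct| \le a$, of duration $2a/c$.
Detection applies, once (one-way), a Gaussian-envelope band-pass impulse
response centred at $f_c = 2.25$ MHz whose $-6$ dB fractional bandwidth is
0.95 (the measured element spectrum is not available, so a Gaussian band-pass
is the modeling choice). Spheres at or below 0.1 mm radius are handled
analytically: in the small-source limit the detected waveform is the time
derivative of the impulse response scaled by $A a^3/(3 r c^2)$, which avoids
sampling aliasing for sub-sample N-waves.

The element's elevational behaviour is modeled, by default, by integrating
`n_sub` point receivers across the 5 mm element height (`directivity =
"aperture"`). This reproduces the far-field sinc directivity of a uniform
line aperture — FWHM $2\arcsin(1.8955\,\lambda/(\pi L))\approx 9.2°$ at
2.25 MHz, matching the system's quoted ~9.0° divergence — and, crucially,
the near-field arrival-time smearing across the element height that limits
3D elevational resolution. Amplitude-only point-element models (`"sinc"`,
`"gaussian"`) are available as fast approximations; they reproduce the
divergence cone but not the time smearing (they make the 3D elevational PSF
about 20% too narrow). Speed of sound defaults to 1.50 mm/µs (water near
35 °C) and is configurable; noise is additive white Gaussian per sample (the
12-bit quantization of the data acquisition is not modeled).

## Reconstruction (`reconstruct_2d`, `reconstruct_3d`)

Both modes use the universal back-projection (UBP) term
$b(t) = 2p(t) - 2t\,\mathrm{d}p/\mathrm{d}t$, evaluated at the acoustic delay
from each pixel to each element (linear interpolation at the native 40 MHz
sampling; central-difference derivative) and weighted by the element's
subtended solid angle ($\cos\gamma / d^2$ for a point-like element with
in-plane inward normal). *Half-time* reconstruction truncates each channel to
propagation distances up to the ring diameter — the minimal early data
sufficient for the field of view, suppressing late-arriving reflections; the
flag can be disabled for full-time UBP. Out-of-record delays contribute zero.

The full ring spatially samples a source at radius $r$ adequately only below
$f_{\mathrm{cut}}(r) = N c / (4 \pi r)$; with 512 elements and the
transducer's upper band edge this gives an unfiltered zone of roughly
37–39 mm diameter. The anti-aliasing option low-pass filters the channel
data into a bank of radius bins (raised-cosine rolloff) and back-projects
each pixel from the copy filtered at its own radius.

The 3D mode back-projects all elevational steps simultaneously, weighting
each contribution by a Gaussian profile of the voxel's elevational angle
(FWHM 9.0°, hard cutoff 18°, both configurable). With `virtual_transducer =
TRUE` (default) delays and angles are computed from a virtual element placed
at the Fresnel–Fraunhofer transition depth $L^2/(4\lambda_c)\approx 9.4$ mm
in front of the physical element; the wavelength convention (centre
frequency) is a design choice.

Measured on simulation (the acceptance script recomputes these): in-plane
PSF FWHM ≈ 251 µm on a 25 µm grid; 3D elevational PSF FWHM ≈ 5.4 mm for a
±15 mm, 1-mm-step scan; 2D-mode elevational sensitivity FWHM ≈ 17 mm.

### Measuring the 2D-mode elevational sensitivity

The 2D mode's elevational resolution is set by the element divergence cone:
a source at elevational offset $z$ contributes signal attenuated by the
directivity at angle $\theta \approx z/r$. The package measures this as the
per-slice peak *detected* amplitude versus source offset, after narrow-band
filtering at the centre frequency where the divergence is defined
(`elevational_sensitivity_profile(method = "divergence")`), giving ≈ 17 mm
at the centre — about 3× the 3D figure. A coherent alternative — peak of the
2D *reconstruction* versus offset (`method = "reconstruction"`) — measures a
different quantity: reconstruction of an off-plane on-axis point is
interferometrically sensitive to the focusing mismatch $z^2/(2R)$ (about
$\lambda/8$ at $z \approx 4$ mm), so that profile collapses to ≈ 8 mm under
every element model. It reflects coherent defocus, not the divergence cone,
and is therefore not the number usually quoted as "2D-mode elevational
resolution"; both estimators are exposed.

## Vessel analysis

`frangi_vesselness` is a standard multi-scale Hessian ridge filter; scales
σ ∈ {1.5, 2.5, 3.5, 4.5, 6} px span vessel diameters of roughly 3–12 px at
the 0.1 mm reconstruction pixel, with α = β = 0.5 and the structure-strength
scale set to half the per-scale maximum. Segmentation uses an adaptive
threshold (local mean over a 51 px window plus 0.5 local SD, with a small
absolute floor so empty slices stay empty), followed by removal of isolated
single pixels. None of these constants are prescribed by the processing
chain being reproduced; they are recorded in the mask's provenance.

Skeletons are extracted by Zhang–Suen thinning; skeleton pixels with more
than two 8-neighbours are junction pixels; removing them splits the skeleton
into independent segments and segments shorter than 3 px are discarded
(≈ the 255 µm resolution divided by the 100 µm pixel).

Diameters are measured by normalized cross-correlation against a bank of
*simulated-and-reconstructed* vessel templates (0.5–2.0 mm in 0.1 mm steps,
several orientations), with parabolic refinement over the diameter grid.
A best match at the bank boundary, or a best correlation below 0.5, raises a
warning: a vessel much wider than 2 mm images as two edge fringes (its
interior is DC and outside the band), so the correlation is *not* monotone
in diameter and out-of-range vessels cannot be meaningfully saturated to the
boundary value. The junction exponent $X_B$ solves
$D_p^X = D_a^X + D_b^X$ by bisection on $[0.5, 10]$; $R_B =
D_p^3/(D_a^3+D_b^3)$. Murray's law corresponds to $X_B = 3$.

## Heartbeat-band artery mapping

Frames with uncorrectable motion are removed first: each frame is globally
aligned to the first frame by phase correlation and dropped if the residual
correlation is below 0.85 (rigid jitter is correctable and should not cause
rejection, which is why the criterion is evaluated after the global rigid
fit). The field is then split into 16 slightly overlapping subdomains (4×4,
25% linear overlap) and each frame is rigidly registered (translation by
phase correlation, small rotation search) to the first retained frame,
blending overlaps with linear ramps. After 0.2 mm Gaussian smoothing, each
pixel's time series is demeaned, Hann-windowed and Fourier transformed; the
band power integrates the spectral magnitude over 1.0–1.6 Hz. Arteries are
vessel pixels whose band power exceeds 3× the median band power over vessel
pixels — the underlying chain classifies by fluctuation magnitude without a
stated cutoff, so the `k_artery` rule is this package's choice — and the
heart rate is the in-band global spectral peak.

## Elastography

Breathing-induced deformation is quantified between vessels. Frames are
registered to the first frame by a fluid-like demons scheme: the update
(intensity mismatch along the fixed-image gradient, clamped to 1 px) is
smoothed, not the accumulated field, preserving stiffness contrast at
inclusion boundaries; iteration stops early when the residual plateaus, and
warm starts exploit temporal coherence. The per-pixel temporal STD of the
registered intensities defines "stably registered" pixels. The field is
divided into 2 mm × 2 mm squares (20×20 px) and one qualifying pixel is
drawn per square (seeded).

Two deliberate deviations from the obvious defaults, both forced by
measurable artifacts at desk scale:

* **STD cutoff = median, not the 20th percentile.** Resampling during
  registration attenuates additive sensor noise in proportion to the local
  displacement's fractional pixel offset, so the *least displaced* tissue —
  the stiff inclusion — systematically shows the *highest* registered STD.
  A 20th-percentile cutoff then leaves the inclusion without stable pixels.
  The cutoff remains a parameter.
* **Structured triangulation, not Delaunay.** Selected pixels form a regular
  grid of squares; two triangles per 2×2 block of adjacent squares give a
  valid, non-degenerate triangulation directly (no Delaunay library is
  required and triangle shape is equally well controlled).

Triangle vertices are mapped into every original frame through the
displacement fields and signed areas tracked; the amplitude of the relative
area series at the discrete bin nearest the compression frequency (Hann
window, with the broadband noise floor estimated from out-of-band bins and
subtracted — this debiases triangles in poorly textured regions) is painted
onto the triangle's pixels. The procedure repeats for `n_realizations`
random stable-pixel draws (default 100) and the final map is the mean.
For phantom work the compression frequency is the configured ~0.25 Hz; for
free-breathing data it can be estimated from the global mean-area spectrum
peak in 0.1–0.5 Hz. `localize_stiff_regions` smooths the map (normalized to
the covered region), thresholds between the 5th/95th percentile floor and
plateau, and reports connected low-deformation regions; a map without
meaningful contrast reports none.

## Vessel density and tumor segmentation

A 2 mm × 2 mm window (exactly 20×20 px at 0.1 mm) scans the image; the
number of distinct independent segments intersecting the window (a segment
partially inside counts once) is assigned to the window centre and divided
by the window area. Whole-breast statistics are computed over a circular
support (10 cm diameter by default; desk-scale phantoms use a support
matched to their vascularized extent). Suspicious regions are 8-connected
components above mean + 2 SD; components below 1855 px (18.55 mm²) are
rejected; each surviving region reports its pixel count, centroid and
longest dimension. Density-ratio ROC analysis sweeps a threshold on the
high/normal density ratio from 1 to 6 in steps of 0.01 (the sweep step is a
choice; on tie-free data the trapezoidal AUC equals the Mann–Whitney
statistic exactly), for high-density definitions at 1.5, 2.0 and 2.5 SD.
The "normal" region is defined as the support pixels not in the high-density
region, and the whole-breast statistics include in-tumor pixels.

## Synthetic phantoms: what they emulate and what they do not

* `generate_vessel_tree` builds planar binary trees whose bifurcations obey
  the planted junction law exactly — the ground truth for morphometry.
* `scatter_vessels` emulates an evenly vascularized cross-section (or a
  chopped-fiber phantom) as short thin segments placed by a hard-core
  process (minimum centre separation), which matches spaced microvascular
  growth and keeps segments resolvable at the 255 µm resolution.
* `rasterize_phantom` plants a tumor as a disc of excess microvessels plus a
  reduced stiffness factor (the tumor contrast mechanisms are elevated
  vessel density and reduced compliance). The background density reference
  is the vascularized region (convex hull of segment midpoints), so the
  multiplier means "times the surrounding tissue's density". The planted
  *count* multiplier must exceed the target *measured* density ratio:
  overlapping microvessels merge at the imaging resolution, and the
  default pipeline (multiplier 6) yields measured high/normal density
  ratios of ≈ 3.3–4.3, i.e. the 3.4 ± 1 range expected for tumors.
* `generate_dynamic_frames` warps with cubic (Catmull–Rom) interpolation and
  replicated edges; bilinear warping introduces texture-dependent intensity
  errors several times larger than a 2% area-change signal, and zero padding
  creates a spurious dilating dark rim. Compression uses
  divergence-consistent displacement fields, so the local relative-area
  amplitude equals the configured amplitude times the local stiffness
  factor by construction.

The default *study conditions* for the end-to-end tumor-detection pipeline
are a 32 mm field at 0.1 mm pixels (320², chosen so simulations stay in the
tens of seconds while the tumor occupies a realistic ~7% of the support
area, as a 1–3 cm tumor does in a 10 cm support), a 30 mm vascularized disc
at 0.3 segments/mm², and a planted 9 mm tumor. Under these conditions the
full chain (simulate → reconstruct → segment vessels → density map →
threshold) localizes the tumor to within ~1 mm in 10/10 seeded runs.

What the phantoms do *not* emulate: acoustic heterogeneity and reflections,
laser fluence distribution and skin optics, out-of-plane vasculature in 2D
frames, vessel tortuosity and diameter taper within segments, and
physiologic motion beyond rigid jitter plus the planted periodic modes.
Passing tests on these phantoms therefore validates the numerics and the
recovery logic of each stage, not clinical performance.

## Numerical choices and degenerate inputs

* Delays interpolate linearly; sub-sample point sources use the analytic
  band-limited waveform; the junction-exponent bisection stops at
  $|f| < 10^{-12}$ (well inside the documented $10^{-9}$).
* FWHM measurement uses linear interpolation at half of (max − baseline)
  with the baseline from the outer 10% of samples; flat profiles and
  boundary peaks are errors.
* Empty inputs return empty results (all-zero sinograms, empty masks, empty
  segment sets, zero density maps); degenerate statistics (zero SD) produce
  a warning and no regions; a constant frame sequence yields a zero
  deformation map.
* All randomness is seeded; identical seed + configuration gives identical
  outputs (the run manifest records md5 checksums).

## Known limitations

* The forward model is single-scattering in homogeneous medium; speed of
  sound is global.
* The demons registration is single-resolution with a 1 px/iteration step
  cap: displacements much larger than a few pixels per frame need a coarser
  initial alignment first.
* Template-matching diameters are reliable only inside the bank's 0.5–2.0 mm
  range (see above for why saturation at the boundary is not achievable).
* The 1855 px region filter and the 10 cm support default are tied to the
  0.1 mm pixel convention; both are parameters.
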