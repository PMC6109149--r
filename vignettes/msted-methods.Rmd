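---
title: "Modulation-enhanced STED analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modulation-enhanced STED analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msted)
```

## The measurement principle

A STED microscope silences fluorophores at the periphery of the excitation
spot with a doughnut-shaped depletion beam, so its resolution is *tunable*:
the harder the depletion, the smaller the effective point spread function
(PSF). `msted` analyses image stacks in which the depletion power is ramped
across the `n` frames of a single acquisition (modulation-enhanced STED,
M-STED). Under the standard parabolic approximation of the doughnut, a
molecule at distance $r$ from the PSF centre emits

$$ i(r) = i(0)\, e^{-2r^2/w_c^2}\, e^{-\zeta\, r^2/w_c^2}, $$

where $w_c$ is the confocal $1/e^2$ waist and $\zeta$ is the depletion
intensity in units of the saturation intensity, evaluated at $r = w_c$
(`sted_psf()`). With a linear ramp $\zeta_j = k\,(j-1)/(n-1)$ the signal of
that molecule decays *exponentially in the frame index*, with a per-frame
rate $\gamma(r) = \gamma_0 + k\,(r^2/w_c^2)/(n-1)$ that grows quadratically
with its distance from the PSF centre ($\gamma_0$ is the excitation-decay
rate, zero for constant excitation). Molecules at the centre keep emitting;
molecules at the periphery dim rapidly. Radial position inside the PSF is
thus encoded in per-pixel *depletion dynamics*, and decoding that code is
what the rest of the package does:

* `compute_phasor()` maps each pixel's frame-wise counts to its
  first-harmonic Fourier coefficients $(g, s)$ normalised by the summed
  counts — the *phasor*. Constant pixels sit at the origin; fast decays
  approach $(1, 0)$.
* `fit_saturation()` recovers $k$ from the image-averaged depletion curve,
  $\langle F_j\rangle/\langle F_1\rangle = 1/(1 + \tfrac{k}{2}
  \tfrac{j-1}{n-1})$, giving the effective resolution of the last frame
  through $w = w_c/\sqrt{1 + k/2}$ (`effective_waist()`) without any
  instrument calibration.
* `split_two_component()` projects each pixel's phasor onto the axis
  between a centre reference $P_{in}$ and a periphery reference $P_{out}$
  and multiplies the resulting centre fraction $f_{in}$ into a chosen STED
  frame, producing the sharpened SPLIT image $F_{in}$.
* `split_three_component()` additionally separates STED-induced background
  (direct excitation by the depletion beam), which rises linearly along the
  ramp, after the excitation has been modulated as
  $e^{-(j-1)/\tau_{exc}}$ to displace the centre dynamics away from the
  background's phasor direction.
* `apparent_size_ics()` and `fit_size_extrapolation()` implement
  spot-variation sizing: across images with different relative PSF sizes
  $w/w_c$, the apparent object size obeys
  $\Sigma^2 = \sigma^2 + 2\ln 2\, w_c^2 (w/w_c)^2$, so a straight-line fit
  returns the true size $\sigma$ (intercept) and the confocal waist $w_c$
  (slope) — again self-calibrated.

## Reference-phasor placement and the SPLIT calibration

SPLIT needs $P_{in}$ and $P_{out}$. They are placed from the data
(`select_references()`): the cloud's elongation axis $\phi_0$ is the
intensity-weighted principal axis through the origin; $M_{in}$ is a low
percentile (default 1st) of the modulation histogram — a robust stand-in
for the minimum observed modulation, which in crowded samples detaches from
zero because even focus centres collect modulated light from neighbouring
foci; and $M_{out} = M_{in} + M_0$ with

$$ M_0 = \frac{m_0}{2}\, \frac{\Delta_N}{|\Delta_M - \Delta_N|}, $$

where $\Delta_M$ and $\Delta_N$ are the cloud's spreads along and across
the elongation axis. $\Delta_M$ grows with the encoded modulation,
$\Delta_N$ with the noise; when $\Delta_M \approx \Delta_N$ the spatial
information is hidden in the noise and `estimate_m0()` refuses SPLIT
(relative excess below `tol`, default 5%) — the stack then still yields the
quantitative outputs $k$ and $B$, and `run_pipeline()` degrades gracefully
to that quantitative-only mode. The user constant $m_0$ (default 1) trades
sharpening against noise amplification; scanning it is also how the
spot-variation analysis obtains images with different effective PSFs from
one stack.

Whether the cloud spreads are intensity-weighted was an open choice; we
weight by pixel total counts (dim pixels carry the noisiest phasors) and
expose `weights = "none"`.

## The effective PSF of a SPLIT image

No closed form is available for the PSF of $F_{in}$, so
`effective_split_psf()` constructs it numerically: the radial profile of an
emitter in $F_{in}$ is the maximum-power STED PSF weighted by
$f_{in}(P(\gamma(r)))$, where $P(\gamma)$ is the theoretical phasor of a
discrete exponential decay (`theoretical_phasor()`) and $f_{in}$ the same
clamped projection used on the data — with the *same* references that
produced the image. A Gaussian $A\,e^{-2r^2/w^2}$ fitted to this profile
defines $w/w_c$. When no data-driven references exist, the periphery
reference is placed at the theoretical decay of a molecule at $r = w_c$
(rate $\gamma_0 + k/(n-1)$); the choice of that radius is a convention —
the analysis never needs the decay rate "of the periphery" at more than one
reference point, and $r = w_c$ is where the saturation factor $k$ is
defined. A scan of alternative radii changed downstream results only
marginally, so the convention is kept throughout (it is also the rate used
for the three-component references).

Because prediction and image share the reference geometry, tighter
references sharpen both consistently, and the spot-variation regression
closes the loop end to end: simulated point-emitter stacks at
$k \in \{2, 4, 6, 8\}$, SPLIT at $m_0 \in \{0.6, 1, 1.6\}$, ICS apparent
sizes and the $\Sigma^2$ vs $(w/w_c)^2$ regression recover the simulated
200-nm confocal waist to within a few percent with an intercept consistent
with zero (point-like emitters). This is the package's strongest internal
consistency check, exercised by the test suite and `scripts/acceptance.R`.

## Three-component unmixing and its limits

For modulated-excitation stacks the references are
$P'_{in} = P(\gamma_0)$, $P'_{out} = P(\gamma_0 + k/(n-1))$ and
$P'_{bkgd}$, the phasor of the linear ramp $(j-1)/(n-1)$
(`background_phasor()`). Each pixel solves the exact $3\times 3$ system
"two phasor coordinates plus normalisation" — algebraically the same as
the classical coordinate change that moves the background phasor to the
origin, but making the out-of-simplex policy explicit: negative fractions
are clamped to zero and the rest renormalised (`negative = "mask"` is
available). Collinear references (which occur exactly when the excitation
is *not* modulated, the failure mode the modulation exists to avoid) raise
an error.

Two caveats are worth knowing. First, real pixels contain a *continuum* of
decay rates, and a curved one-parameter phasor family represented by two
points leaves intermediate rates slightly off the $P'_{in}$–$P'_{out}$
chord; the solver absorbs the deviation partly into $f_{bkgd}$, so
background fractions near bright structure edges are biased low by a few
percent. Second, the fractions refer to shares of the *stack-summed*
signal, because the phasor is a whole-stack transform; comparisons with a
per-frame ground truth must use stack-total fractions. Within those limits,
simulations with a 20% background level recover the injected doughnut
fraction field with correlation above 0.9.

The `clamped_fraction` diagnostic reports the share of *unmixed signal*
(not of pixels) whose raw solution left $[0, 1]$: the dim far periphery
always projects beyond $P_{out}$ by construction, so a pixel count would be
alarmingly large while the affected signal is typically ~10% on nominal
data.

## The simulator: what it emulates and what it does not

`simulate_msted()` reproduces the reference simulation conditions used for
validation: point-like emitters placed uniformly in a 16-µm circle,
512×512 frames of 40-nm pixels, $w_c = 200$ nm, an 8-frame linear ramp,
global scaling so the brightest confocal-frame pixel has expectation
`s_max` (default 30; 40 in the background scenarios), independent Poisson
counts, and optionally a STED-induced background whose per-frame amplitude
grows linearly to `b_max_percent` of `s_max`. The background halo is the
vortex doughnut $(r^2/w_c^2)\,e^{-2r^2/w_c^2}$ centred on each emitter and
peak-normalised over the field — attaching the background to the emitters
(rather than to a separate fluorophore map) is an assumption; only the
halo's temporal linearity matters to the analysis. Density defaults are one
design choice made once: 150 sparse foci (≈0.75 µm⁻²), 1500 crowded foci
with $w_c = 400$ nm, discs 10 px across for large foci, and filaments as
smooth random walks (half-pixel steps, 0.06 rad heading diffusion).
Emitters are splatted to their nearest pixel by default; bilinear splatting
is available when sub-pixel geometry matters (e.g. resolution benchmarks at
separations that are not grid multiples).

The simulator deliberately omits photobleaching, detector afterpulsing,
drift, optical aberrations and 3-D effects. Tests passing on it therefore
demonstrate the correctness of the *decoding chain* under the model's own
assumptions and Poisson statistics — not robustness to every property of
real data.

## Numerical choices

* **Depletion fits** use `minpack.lm` weighted least squares with
  frame-summed counts as weights (the inverse Poisson variance of a frame
  mean); the paper-level models never need more than two parameters because
  $\gamma_0 = 1/\tau_{exc}$ is protocol-known and is held fixed — fitting
  it jointly with $(k, B)$ is degenerate at typical $n$.
* **Phasor smoothing** is a 3×3 median filter on the $g$/$s$ images (never
  on counts), standard phasor practice; radius 0 disables it. The
  spot-variation scan runs unsmoothed: median filtering correlates
  neighbouring pixels and would widen the ICS autocorrelation, whereas
  unsmoothed shot noise lives only in the zero lag, which the ICS fit
  excludes.
* **Foreground threshold**: pixels with fewer than 10 summed counts are
  masked (their phasors are noise); masked pixels yield zero, not `NaN`.
* **ICS sizing** fits an isotropic Gaussian plus offset to the normalised
  autocovariance, excluding the zero-lag shot-noise spike, over lags within
  3× the initial width guess; the correlation $1/e^2$ radius converts to
  the spot waist via $\omega = \sqrt{2}\,w$ and to the reported size via
  $\Sigma = \sqrt{2\ln 2}\,w$. The implementation is pinned by an oracle
  test against per-spot Gaussian fits on synthetic fields.
* **Frame-time convention**: $t = j - 1$, $T = n - 1$, so frame 1 is
  exactly confocal and frame $n$ carries $k$.
* **Angles at exact multiples of $\pi/2$** in the phasor basis are snapped
  to 0/±1 so that, e.g., two-frame stacks have an identically null $s$.
* **Harmonic**: analyses default to the first harmonic; higher harmonics
  are supported (`harmonic` argument) but carry less signal for these
  decays.

## Problem sizes used in the shipped checks

The packaged tests validate unit behaviour on 64–256 px fields and the
end-to-end claims at the full 512×512 reference geometry; the acceptance
script simulates five 512×512 stacks (saturation recovery at two SNRs and
the four-point spot-variation scan with three $m_0$ values, twelve size
points). These sizes reproduce the reference statistics — depletion-curve
averages over ~2.6×10⁵ pixels make the fitted $k$ precise to ~1% — while
keeping a complete run in the tens of seconds.

## Known limitations

* The parabolic doughnut approximation underlies every closed form; real
  vortex beams deviate at large $r$, so experimental $k$ values are
  effective parameters.
* Reference placement assumes one dominant decay family; multi-species
  samples with different depletion cross-sections would need per-species
  references.
* The three-component solve is exact for three decays but only approximate
  for the continuum (see above); a pixel-wise maximum-likelihood temporal
  unmixing is out of scope.
* Sizes from ICS describe the *average* spot; per-focus size distributions
  are not produced.
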