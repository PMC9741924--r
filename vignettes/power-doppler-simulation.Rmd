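---
title: "Modeling power-Doppler perfusion imaging: echo simulation, registration and eigenfiltering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling power-Doppler perfusion imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdus)
```

## The problem

Power-Doppler ultrasound estimates tissue perfusion from the net echo power
that remains after tissue (clutter) and noise components have been filtered
out of a slow-time ensemble of pulse-echo frames. In peripheral muscle the
blood moves at capillary speeds (0.1–2 mm/s) in largely random directions,
while the much more echogenic muscle tissue moves quasi-rigidly with
breathing and cardiac pulsation. Because the tissue-to-blood amplitude ratio
is an order of magnitude or more, even small clutter motion spreads clutter
energy across the eigenspectrum of the ensemble and contaminates the blood
signal. `pdus` implements a complete computational model of this measurement:
a discrete-scatterer echo simulator with known ground truth, a two-stage
speckle-tracking registration stage that removes in-plane clutter motion, an
SVD (principal-component) clutter filter, and the coherence-based Cramér–Rao
bounds used to validate the displacement estimator.

## Echo model

Tissues are modeled as random point scatterers: tissue scatterers with
reflectivity $\tau$ fill the volume, and blood scatterers with reflectivity
$\beta = 1$ additionally fill a perfusion region, both as Poisson point
processes with equal number density. An echo sample at lateral position
$x_\ell$ and depth $z_k$ in frame $m$ is the coherent sum

$$ g_{k\ell m} = \epsilon_{k\ell m} + \sum_n a_n\, h_G(\mathbf{x}_n(t_m) - \mathbf{x}_{k\ell}), $$

where $h_G$ is a Gabor approximation to the pulse-echo spatial sensitivity
function: a carrier $\sin(2\pi u_0 z + \phi)$ times a separable Gaussian
envelope with widths $(\sigma_x, \sigma_{y,\mathrm{amp}}, \sigma_z)$. Frames
are instantaneous (scatterers are frozen during one frame) and the pulse is
shift-invariant across the frame. Acquisition noise is i.i.d. zero-mean
Gaussian, calibrated so the mean noise-free signal power over the ensemble
divided by the noise variance equals the requested echo SNR.

All dependent pulse parameters derive from four independent ones
($f_0$, fractional bandwidth, sound speed $c = 1.54$ mm/µs, f-numbers):

```{r}
pulse_spec(5, 0.75)
```

Two presets mirror the standard study conditions: a broadband 5-MHz pulse
processed as real RF at 30 dB echo SNR, and a broadband 20-MHz pulse
processed as complex IQ (demodulated, low-pass filtered and decimated by 5,
giving an effective 25.7-MHz fast-time rate) at 15 dB SNR. The
tissue-to-blood amplitude ratio is 16 (24.1 dB) at 5 MHz and 5 (14 dB) at
20 MHz.

### The elevational width

The Gabor envelope's elevational *amplitude* width is set to
$\sigma_{y,\mathrm{amp}} = \sqrt{2}\,\sigma_x$, so that the interframe echo
correlation under an elevational shift $\Delta y$ is
$\exp(-\Delta y^2 / 2\sigma_y^2)$ with the tabulated $\sigma_y = 2\sigma_x$.
This choice is forced by the quantitative behavior the model must reproduce:
it yields $\rho(y) = 0.5$ crossings at 0.617 mm (5 MHz) and 0.154 mm
(20 MHz), and makes the 95%-energy ellipsoid of the envelope equal the
closed-form speckle correlation volume $A_{3D}$ within about 1%. The
alternative reading $\sigma_{y,\mathrm{amp}} = 2\sigma_x$ fails both checks.

### Spectral convention

The axial spectral width in the parameter table,
$\sigma_z = \sqrt{2\ln 2} / (\pi\,\mathrm{FWHM}_{u_z})$, is numerically
consistent only with $\mathrm{FWHM}_{u_z}$ measured on the *amplitude*
spectrum $|H(u_z)|$; the package adopts that convention throughout, so
$|H(u)|^2$ carries frequency standard deviations $1/(2\pi\sigma)/\sqrt{2}$.

## Motion programs

Clutter moves rigidly: either a linear translation or an elliptical in-plane
oscillation (default 1 Hz with 0.05 / 0.025 mm half-amplitudes — amplitudes
chosen to respect the sub-0.1-mm motion observed in fixed-probe resting
acquisitions; the published oscillation figure prints no amplitude). Blood
velocities are superposed on the clutter velocity: *directed* flow draws each
cell's direction once, uniformly inside a ±15° cone about the beam axis;
*diffuse* flow draws directions uniformly on the sphere, so the spatial-mean
blood velocity vanishes. Directions are frozen per cell for the whole
ensemble: the motion description is of constant-speed cell tracks, and no
re-randomization interval is stated anywhere, so the least-assumption reading
is ballistic motion. This choice matters quantitatively: it sets the
slow-time coherence of the diffuse blood signal and therefore how many
eigencomponents the blood subspace spans (see *Known limitations*).

Scatterers that drift out of the volume are neither wrapped nor respawned;
wrap-around would create phantom coherence, and the 2-mm guard margin far
exceeds any drift accumulated over a 2-s ensemble.

## Registration

Displacement of frame $m$ relative to frame 1 is estimated in two stages per
analysis window (default: nine 2 × 2 mm windows in a 3 × 3 plan; 1 × 1 mm
windows are a config option):

1. **Coarse:** integer-lag argmax of the zero-padded FFT cross-correlation,
   ties broken toward the smaller lag norm.
2. **Fine:** maximization of the continuously interpolated correlation
   coefficient by a Nelder–Mead simplex search (convergence criterion
   $10^{-4}$ in samples), with the remainder clamped to ±1.5 samples.

The fine stage evaluates the correlation at fractional lags by *exact
band-limited (trigonometric) interpolation* of the full-overlap correlation
computed against a frame-m patch that extends beyond the window, so there is
no shrinking-overlap (triangular) bias. The correlation is normalized by the
sliding energy of the moving patch: with a plain (unnormalized) correlation
the local speckle-energy gradient across a window containing only a few
speckle cells displaces the peak by a noise-independent ~0.5 samples, which
would dominate every error budget. The reference window is tapered (squared
Tukey weights, 40% taper) so both the correlation and the sliding-energy lag
sequences decay smoothly at their support edges; with a hard-edged window the
energy sequence's support cliff rings under trigonometric interpolation and
biases the lateral peak by a few $10^{-3}$ samples. After these choices the
fine stage reproduces a zero shift to about $10^{-4}$ samples axially and
$10^{-3}$ laterally on noise-free speckle.

Frames are aligned to frame 1 by resampling at grid points offset by the
(window-averaged) estimate, using a separable Fourier phase shift with mirror
extension. Spline or convolution kernels leave roughly −30 dB of
interpolation residue on RF sampled at ~7.7 samples per carrier period;
because clutter sits ~24 dB above blood, such residue would masquerade as
clutter-filter leakage, while the band-limited shift is exact away from the
frame edges. A 0.5-mm edge guard is excluded from all downstream power
integrals for the same reason. When total travel exceeds a window size
(lateral sweep experiments), displacements are tracked frame-to-frame and
accumulated (`cumulative = TRUE`) before aligning to frame 1.

For the component power states (`net_power_report`,
`power_state_experiment`), displacement is estimated **once** from the
clutter-bearing combined signal and the same alignment is applied to every
component state. Registration tracks the echogenic clutter; self-registering
a blood-only directed-flow state would instead lock onto and remove the
blood's own coherent motion, collapsing the blood into the first
eigencomponent and destroying the power accounting. `alignment = "self"`
remains available for comparison.

## Clutter filtering and power states

The registered ensemble is unfolded into a Casorati matrix (ROI pixels ×
frames) and decomposed by SVD. The clutter filter retains an eigenindex band
(e.g. 2–6 or 2–11 of 21) and reconstructs; the Doppler spectrum is the
ROI-averaged slow-time periodogram (boxcar taper by default — 21 frames are
too short to spend on sidelobe control), and *net power* is its integral over
the full measurement bandwidth, equal by Parseval to the mean sample power.
The velocity axis uses $v = (c/2)\, f_D / f_0 = f_D / u_0$. Powers are
reported in dB relative to the unfiltered, unregistered blood-only state, the
natural 0-dB reference for perfusion accuracy.

## Variance bounds

For jointly wide-sense-stationary frame pairs in band-limited white noise,
the displacement-variance lower bounds are one-sided spectral integrals

$$ \mathrm{var}(\hat\xi) \ge \Big[ 8\pi^2 X_0 \int_0^\infty du_x\, u_x^2\, S(u_x) \Big]^{-1}, $$

with the axial analog in $Z_0$ and $S(u_z)$, where
$S(u_x) = B_x (\sigma_f^2/\sigma_\epsilon^2) \int_0^\infty du_z |H(u)|^2$ is
the marginal signal-to-noise spectrum and the scale
$\sigma_f^2/\sigma_\epsilon^2$ is fixed by the echo SNR through the
one-sided integral of $|H|^2$ (so the arbitrary normalization of $H$
cancels). Closed Gaussian forms and adaptive quadrature agree to $10^{-8}$
relative; the bounds carry no dependence on the true displacement, scale as
$1/X_0$ (resp. $1/Z_0$), and fall one decade per 10 dB of SNR. At the 5-MHz
preset the quadratic frequency weighting puts the axial bound ≈ 31 dB below
the lateral bound.

One structural caveat is documented rather than hidden: these marginal
bounds treat each axis as a single 1-D record of length $X_0$ (or $Z_0$).
The full 2-D information for a window of area $X_0 Z_0$ is larger by roughly
the number of independent lines across the window ($Z_0 B_z$ laterally,
$X_0 B_x$ axially), and the package's estimator — an efficient normalized
correlator — empirically reaches that two-dimensional limit for SNR
≥ 20 dB. Its measured variances therefore fall *below* the marginal bounds
by roughly those factors, rather than landing on them; the acceptance suite
records this comparison as-is.

## What the synthetic generator does and does not emulate

The generator reproduces: fully developed speckle (≥ 20 scatterers per
resolution cell), the clutter-to-blood amplitude and density ratios, rigid
in-plane and elevational clutter motion, directed and diffuse capillary-speed
perfusion superposed on tissue motion, band-limited white acquisition noise
at a calibrated echo SNR, and the RF vs IQ processing paths. It does not
model: attenuation and frequency-dependent scattering, depth-dependent
focusing or apodization, deformable (non-rigid) tissue motion, vessel-tree
geometry, resolved structures, or transducer element noise correlation.
Passing tests therefore validate the measurement pipeline under ideal
speckle statistics, not performance on heterogeneous in vivo tissue, where
window placement and adaptive filter thresholds become first-order concerns.

## Numerical choices

- **Footprint truncation:** each scatterer contributes within ±3.5σ per
  axis; widening to ±5σ changes samples by at most ~0.7% of frame RMS
  (measured in the test suite).
- **Elevational culling:** scatterers farther than 3.5
  $\sigma_{y,\mathrm{amp}}$ from the scan plane are skipped.
- **Degenerate inputs:** all-zero correlation windows, zero-power noise
  calibration, empty ROIs, and bands exceeding the frame count are errors,
  not silent results.
- **Ties at the coarse peak** break toward the smaller Euclidean lag norm,
  then lexicographically — determinism over elegance.
- **Problem sizes:** the simulation experiments run on reduced frames
  (3–6 mm) wherever the measured quantity is frame-size-independent
  (correlation coefficients, single-window variances); the power-state
  experiments use the full 10 × 10 mm frame, 21 frames at 10 Hz, and ≥ 10
  seeds. The elevational sweeps use 21 positions over 0–1.2 mm (5 MHz) or
  0–0.3 mm (20 MHz); the scaling experiment uses the five window areas from
  0.5 × 0.5 to 2.5 × 2.5 mm.

## Known limitations

- The diffuse-blood slow-time coherence under frozen ballistic directions
  concentrates ~3/4 of the blood energy in eigenindices 2–6 of a 21-frame
  ensemble, so the registered, SVD-filtered combined signal underestimates
  blood power by ~1 dB (band 2–6) / ~0.3 dB (band 2–11) under these
  conditions — the qualitative ordering of all nine power states reproduces,
  but deeper underestimation would require faster blood direction
  decorrelation than the model commits to.
- The marginal variance bounds are loose for 2-D windows (see above); they
  remain the right validation surface for the published bound expressions.
- Eigenindex thresholds are fixed inputs; adaptive threshold selection is
  out of scope by design.
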