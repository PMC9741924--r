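# pdus — power-Doppler ultrasound simulation, registration and clutter filtering

`pdus` is a computational model of power-Doppler ultrasound (PD-US) for
peripheral-perfusion imaging, for researchers studying how spatial
registration and eigen-based (PCA/SVD) clutter filtering determine whether
blood-echo power can be measured reliably without contrast agents. It
simulates radio-frequency echo ensembles from moving tissue (clutter) and
perfusing blood scatterers with exactly known ground truth, so every stage of
the measurement — displacement estimation, frame alignment, clutter
filtering, Doppler power integration — can be evaluated component by
component.

## The model in brief

Tissue and blood are random point scatterers (Poisson, equal number density,
reflectivity ratio τ/β = 16 at 5 MHz, 5 at 20 MHz). An echo sample is the
coherent sum of a Gabor point-spread function over scatterer positions,

    g[k,l,m] = ε[k,l,m] + Σ_n a_n · h_G(x_n(t_m) − x_kl),
    h_G(x)   = sin(2π u0 z + φ) · [(2π)^{3/2} (2σx²) σz]^{-1}
               · exp(−½((x/σx)² + (y/σy,amp)² + (z/σz)²)),

with i.i.d. Gaussian noise calibrated to the echo SNR. Clutter translates
rigidly (linear or 1-Hz elliptical oscillation); blood-cell velocities
(directed within a ±15° cone, or diffuse with zero mean) are superposed on
the clutter motion. Frames are registered to frame 1 by two-stage speckle
tracking (coarse FFT cross-correlation peak + subsample maximization of the
band-limited-interpolated correlation coefficient), then filtered by zeroing
eigenindices outside a retained band of the Casorati-matrix SVD. Net
Doppler power over the perfused region, relative to the blood-only signal,
quantifies filtering accuracy. Coherence-based Cramér–Rao bounds

    var(ξ̂) ≥ [8π² X0 ∫₀^∞ du_x u_x² S(u_x)]⁻¹,   S = marginal SNR spectrum,

validate the displacement estimator. See the vignette
(`vignettes/power-doppler-simulation.Rmd`) for assumptions, parameter
defaults and numerical choices.

## Worked example

```r
library(pdus)
preset <- pd_preset("5MHz")
print(preset$pulse)

m <- spectral_model(preset$pulse, Bx = 5, Bz = 25, snr_db = 30)
b <- variance_bounds(m)

r <- power_state_experiment(preset, "diffuse",
                            bands = list(c(2, 6), c(2, 11)), seed = 1)
print(r, row.names = FALSE)
print(round(attr(r, "unfiltered"), 1))
```

Output:

```
Gabor pulse: f0 = 5 MHz, frac BW = 0.75, c = 1.54 mm/us
  u0 = 6.494 mm^-1, FWHM_uz = 4.87 mm^-1, FWHM_x = 0.616 mm
  sigma (x, y, z) = (0.2616, 0.5232, 0.07696) mm
  A_2D = 0.3221 mm^2, A_3D = 0.6741 mm^3

    state band power_db_rel_blood
     fr b  2-6         -1.3237387
     fr b 2-11         -0.9752107
   fr b+n  2-6         -0.9459762
   fr b+n 2-11         -0.2973648
 fr c+b+n  2-6         -0.8365729
 fr c+b+n 2-11         -0.1899343
    c     n     b c+b+n
 24.5  -5.4   0.0  24.5
```

Reading the numbers: the derived pulse parameters reproduce the standard
5-MHz table (u0 = 6.494 mm⁻¹, σx = 0.262 mm, ...). The variance bounds `b`
give a lateral displacement standard deviation of 3.7 µm and an axial one of
0.11 µm for a 1-mm window at 30 dB SNR — a ≈ 31 dB lateral/axial variance
gap from the quadratic frequency weighting. In the power table, unfiltered
clutter sits +24.5 dB above blood power (the τ² = 24.1 dB reflectivity ratio
plus speckle fluctuation) and noise at −5.4 dB; after registration and SVD
filtering with eigenindices 2–6, every blood-bearing state recovers blood
power to within ~1.3 dB of the 0-dB truth, with the broader 2–11 band
recovering slightly more.

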