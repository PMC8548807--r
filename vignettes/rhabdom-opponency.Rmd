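---
title: "Modelling red-green opponency in the butterfly rhabdom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling red-green opponency in the butterfly rhabdom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhabdomR)
```

## The system and the model

Nymphalid butterflies carry nine photoreceptors (R1-R9) per ommatidium,
their microvilli fused into a single light guide, the rhabdom. Because all
nine cells absorb from the same propagating flux, each cell's effective
spectral sensitivity is shaped not only by its own visual pigment but by
everything above it: the rhodopsin/metarhodopsin states of all cells
(self-screening), a non-bleaching red perirhabdomal pigment in some
ommatidia, and the tapetal mirror at the base that sends the surviving
photons back up. The package models this as one-dimensional Beer-Lambert
transport through a stack of slabs, coupled to the photochemistry of the
pigments, and pairs the optical model with the analysis tool chain for
intracellular recordings from the green-depolarizing, red-hyperpolarizing
(G+R-) cells that read out the resulting opponency.

### Light transport

The rhabdom (450 µm) is discretized into slabs of dz = 5 µm; spectra live
on a 300-700 nm grid at 1 nm. Each receptor r occupies an area fraction
rho_zr of the cross-section in slab z and carries one
rhodopsin/metarhodopsin isoform pair with peak absorption coefficients
alpha_R = 6 mm^-1 and alpha_M = 7.5 mm^-1; absorbance spectra Gamma(lambda)
are A1-nomogram templates (alpha band plus, by default, the UV beta band —
the measured opponent spectra show a small UV sideband, so the beta band is
on unless disabled). Effective absorption coefficients are

    kappa_zrp = alpha_p * rho_zr * f_zp ,   p in {R, M},  f_R + f_M = 1.

The downwelling flux attenuates slab by slab as
`I_out = I_in exp(-dz * sum_rp kappa_zrp Gamma_rp)`, is reflected at the
tapetum (reflectance 1 by default) and attenuates again on the way up; the
actinic flux driving photochemistry is the bidirectional sum, evaluated at
mid-slab (geometric mean of the slab faces) for second-order accuracy. The
red screening pigment enters as an additional depth-gated, non-bleaching
absorber over 230-420 µm — operationally a tenth "cell" whose state never
changes — with a logistic absorbance (half-fall 600 nm, steepness
0.05 nm^-1) standing in for the measured curve, which is not tabulated
anywhere; it absorbs green and transmits red.

### Photoequilibrium

Per-molecule conversion rates are k_p = alpha_p * integral of
Gamma_p(lambda) I_z(lambda) dlambda (trapezoid rule on the grid), giving
the master equation df_R/dt = k_M (1 - f_R) - k_R f_R with equilibrium
f_R = k_M / (k_R + k_M). The cross-section fraction rho cancels in this
ratio, and for a single slab under monochromatic light the equilibrium
reduces to the closed form alpha_M Gamma_M / (alpha_R Gamma_R + alpha_M
Gamma_M), independent of intensity — both used as test oracles. Because
the pigment state filters the light that sets the pigment state, the
solver iterates {flux -> rates -> f_R} from the dark-adapted state
(f_R = 1) until max |delta f_R| < 1e-3; on the default configuration this
converges in well under ten iterations. An independent ODE path integrates
the same master equation with `deSolve::ode`, with time normalized so that
the largest dark-adapted rate is 1 per time unit (no absolute
photon-to-rate constant exists in this formulation); it is run to t = 400
normalized units because the dimmest (basal) slabs relax two orders of
magnitude more slowly than the distal ones. The two paths agree to
max |delta f_R| ~ 1e-4, well inside the 0.01 the tests require.

A note on formulas: the absorbed-photon rate as sometimes written,
k = integral(kappa Gamma I), contains f through kappa; carrying that f
into both the master equation and the equilibrium ratio would count it
twice and would break the closed form above. The package therefore
evaluates the solver's rates at f = 1 (per-molecule form). Similarly, the
quantum catch is computed in the physically consistent absorbed-photon
form Q_r(lambda) = sum_z I_z kappa_zrR Gamma_rR dz — a catch written as
I * rho * kappa would carry rho twice. Peak-normalized spectra are
insensitive to constant factors either way.

### The cross-section profile

The true depth profile rho_zr comes from unpublished morphology, so the
package ships a documented stand-in: R1/2 each 15% of the cross-section
down to 250 µm, R3/4 each 20% distally rising to 25% where R1/2 vacate,
R5-8 sharing the remainder, and R9 filling the whole cross-section in its
400-450 µm window. `perturb_rho_profile()` applies ±10% multiplicative
perturbations; the headline model outputs (equilibrium fractions, peak
positions, log sensitivity ratio) are insensitive to these, as the
acceptance tests verify — the equilibrium is rho-free by construction, and
peak positions are set by the spectral, not spatial, structure.

### Calibrating the screening pigment density

The study set the screening pigment's peak absorption alpha_S by matching
the modelled exiting flux to measured eyeshine spectra, without printing a
value. Those reference spectra are not available here, so the package
calibrates differently: with the visual pigments alone the modelled
eyeshine is already red-dominated (green is consumed on the double pass
regardless of alpha_S, and the half-rise wavelength sits at ~612 nm even
at alpha_S = 0, moving redward as alpha_S grows — so a half-rise criterion
cannot select a density). Instead alpha_S = 35 mm^-1 was frozen as the
density at which the red-band eyeshine reflectance is ~35% at 650 nm,
matching the bright red eyeshine of red-shining ommatidia
photographed in these species. The R1/R9 log sensitivity ratio depends on
this choice — it grows from ~1.4 to ~2.5 as alpha_S goes from 30 to
80 mm^-1 — which is why that ratio is quoted with its alpha_S dependence.

### Distal versus basal sensitivity: two readings

The model's characteristic result is that the effective sensitivity of the
R545-bearing receptors shifts redward with depth. Two quantitative
readings exist. The *depth-resolved* local catch spectrum
(`depth_resolved_peak()`) peaks at 545 nm in the top slab and beyond
600 nm at the base — matching the narrative "from ~545 nm distally to
above 600 nm basally" exactly. The *partial-sum* reading
(`effective_sensitivity()` with a depth window) integrates the catch over
the distal 0-230 µm or basal 350-450 µm portion; the distal sum peaks near
560 nm, not 545 nm, because even the first 230 µm of a fused rhabdom
self-screen the green: every receptor absorbs at 545 nm, so the deeper
distal slabs see green-depleted light and drag the summed spectrum ~15 nm
redward. This is a structural property — it survives any admissible
cross-section profile, screening density, or slab refinement — and the
package reports the partial-sum peak as computed rather than adjusting
windows to meet the narrative value. Both readings are exposed; the
acceptance suite tests the partial-sum convention and the model test suite
checks the depth-resolved top-slab peak at 545 nm.

## Electrophysiological analysis

Response amplitudes V to isoquantal flashes are fitted with the hyperbolic
sigmoid V = V0 I^n / (I^n + R^n) on the linear intensity scale,
least-squares in voltage (additive-noise convention;
`minpack.lm::nlsLM`). Flashes brighter than -1 log are excluded from the
depolarizing fit, as saturated points carry no shape information. The
fitted parameters invert each response into the equivalent intensity
I_eq = R (V / (V0 - V))^(1/n); since all flashes deliver the same photon
flux, relative sensitivity is proportional to I_eq (a half-maximal
response maps to exactly R, a vanishing response to zero). Responses at
>= 98% of saturation are excluded from inversion with a warning.

Opponent decomposition follows the selective-adaptation logic: the G+
spectrum is the depolarizing sensitivity under red (650 nm) adaptation,
which silences the opponent input; the R- spectrum is the hyperpolarizing
response under green (500 nm) adaptation, inverted through the second
(hyperpolarizing) intensity-response function and reported negative, with
the joint spectrum normalized so the larger-magnitude peak is +1. A cell
whose "second" intensity-response function is not credibly hyperpolarizing
(wrong branch, or a saturating amplitude below four times the residual
noise) is reported as having no R- unit rather than a noise-shaped one.

Polarization runs are inverted to sensitivities first, then fitted with
S(theta) = S_min + (S_max - S_min) cos^2(theta - Phi). Because cos^2 is a
pure second harmonic, this is an exact linear regression on cos(2 theta)
and sin(2 theta); Psi = S_max / S_min and Phi is reported modulo 180
degrees. A vanishing second harmonic is flagged degenerate (Psi = 1, Phi
undefined) instead of being fabricated. Fitting sensitivities rather than
raw voltages follows the analysis order of the source procedures
(transform, then parametrize).

Spectra are summarized by the apex of a least-squares parabola through the
contiguous grid points above 75% of the maximum (at least the immediate
neighbours; a parabola through exactly three points is the classical
special case). The wider band matters on broad peaks, where three-point
interpolation transmits flank noise at several nanometres per millivolt;
on the asymmetric visual-pigment templates the band introduces a bias
below 2 nm, much smaller than the noise it removes. FWHM is the distance
between the two 50%-of-peak crossings found by linear interpolation,
computed on the magnitude of the component spectrum; a secondary peak is
reported when a second local maximum exceeds half of the main one (the
blue+green co-expressing cells). Multiple cells are summarized as mean ±
s.e. after per-cell fitting, never pooled before.

## The synthetic recordings

`opponent_cell_spec()` defines the generative cell: a G+ unit whose
sensitivity is an A1 template (or a weighted sum of two, for the
co-expressing dual-peaked cells) driving the depolarizing sigmoid with the
measured defaults (logR = -2.51, n = 0.86, V0 = 25 mV), and an R- unit
driving a delayed opponent conductance with the measured hyperpolarizing
sigmoid (logR = -1.21, n = 1.05, V0 = 10 mV), a -70 mV reversal potential
and a 20 ms delay. The opponent amplitude scales with the driving force
(V_hold - E_rev), so injected current through the 20 MOhm input resistance
amplifies, nulls, or reverses it — the generator asserts the zero crossing
at V_hold = E_rev by construction. The R- spectral sensitivity is a
Gaussian at the per-species (peak, FWHM) values with a small UV sideband:
the measured opponent spectra are far narrower than any visual-pigment
template because the screening pigment sharpens them, and a Gaussian
carries exactly the two parameters the recovery analysis must return.
Adaptation is divisive — each unit's catch is divided by
1 + strength × S_unit(lambda_adapt) — the simplest mechanism that
reproduces isolation of the R- responses under green light and their
silencing under red. The strength default (5000, ~3.7 log units at unit
sensitivity) makes the isolation essentially complete; at weaker settings
residual G+ depolarization measurably contaminates the hyperpolarizing
intensity-response function, which contradicts the isolation the analysis
(and the printed sigmoid parameters) presuppose. Gaussian noise
(sigma = 0.5 mV) is added per flash.

Protocols mirror the two-source stimulator: spectral scans use the
continuously tunable monochromator grid (10 nm steps, 360-700 nm) while
the LED bank (the 21 published peak wavelengths, `led_wavelengths()`)
provides adaptation; intensity series run -4.5 to 0 log in 0.5 log steps;
polarization runs flash every 18 degrees over three rotations. Flashes are
repeated and averaged (3 by default; 10 for the green-adapted scans, whose
inversion is the noise-critical step), and the benchmark uses 6 cells per
species: with sigma = 0.5 mV the per-cell peak-wavelength precision for
the broadest (60 nm FWHM) opponent spectra is ~4 nm, so species means need
this much averaging to be meaningful at the few-nanometre level. The
red-adapted scan intensity is titrated per cell from observable responses
(`tune_flash_intensity()`), as an experimenter would, because the flat
gain reduction under red adaptation varies strongly between green- and
blue-peaked cells.

What the generator does *not* emulate: photon shot noise (noise is
additive and intensity-independent), response kinetics beyond a fixed
two-step waveform, spikelets, receptive-field structure, dark noise from
tonic transmitter release, and any history dependence of adaptation.
Passing recovery tests therefore show that the analysis chain is correct
and well-powered for data with this statistical structure — not that it is
robust to every pathology of real recordings.

## Numerical choices and problem sizes

- Wavelength grid 300-700 nm at 1 nm (401 points); depth 90 slabs of 5 µm.
  Halving dz changes normalized sensitivities by < 1e-4 sup-norm.
- Fixed-point tolerance 1e-3 on max |delta f_R| (iteration cap 100);
  convergence failure raises an error carrying the last delta.
- ODE: `lsoda` defaults, duration 400 normalized units, 41 saved points.
- Trapezoid quadrature for all wavelength integrals; agreement with a
  0.1 nm oracle quadrature is tested to 0.1%.
- Photon bookkeeping (absorbed + exited = source) holds to machine
  precision by computing per-slab absorption as entering minus exiting
  flux.
- Sigmoid fits: Levenberg-Marquardt, V0 bounded positive, n bounded below
  at 1e-3; degenerate inputs (constant responses, < 4 levels) error out.
- The acceptance workflow runs the full model once (~0.2 s), the ODE
  cross-check once, a 100-cell estimator benchmark, and one 6-cell-per-
  species recovery pipeline.

## Known limitations

- The optical model is one-dimensional: no waveguide modes, diffraction,
  angular structure or birefringence, matching the source model's stated
  scope.
- The screening-pigment spectrum is a logistic surrogate, not the measured
  absorbance; quantities that depend on its exact red tail (most visibly
  the R9 peak position and the R1/R9 log ratio) inherit that uncertainty.
- alpha_S is calibrated to eyeshine magnitude, not to a measured spectrum;
  the log-ratio's dependence on it is documented above.
- The distal partial-sum peak is structurally ~560 nm under the stated
  windows; see the two-readings discussion.
- Absolute sensitivities are per unit corneal flux and arbitrary common
  scale; only ratios and normalized spectra are meaningful.
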