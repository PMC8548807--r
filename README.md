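# rhabdomR

Light transport and photoconversion in the fused rhabdom of nymphalid
butterflies, plus the electrophysiological analysis chain for the
green-depolarizing / red-hyperpolarizing (G+R−) photoreceptors that read
out the resulting red–green opponency.

Butterfly ommatidia stack nine photoreceptors (R1–R9) along a single
450 µm light guide. What each cell "sees" depends on everything above it:
the rhodopsin/metarhodopsin states of all cells filter the downwelling
light (self-screening), a non-bleaching red perirhabdomal pigment blocks
green in the proximal rhabdom, and the basal tapetum reflects the
remainder back up (producing the eyeshine). The package answers two
questions with one toolset: *what spectral sensitivities does this optical
stack predict for each receptor — in particular for the minute basal R9
that supplies the red opponent signal?* and *can the analysis procedures
applied to intracellular recordings recover the underlying parameters?*

## The model

For slab `z`, receptor `r` and pigment isoform `p ∈ {R, M}` with area
fraction `ρ_zr` and isoform fraction `f_zp` (`f_R + f_M = 1`):

    κ_zrp = α_p ρ_zr f_zp                      effective absorption, mm⁻¹
    I_out = I_in · exp(−dz Σ_rp κ_zrp Γ_rp)    slab-by-slab transport
    k_p   = α_p ∫ Γ_p(λ) I_z(λ) dλ             per-molecule conversion rate
    df_R/dt = k_M (1 − f_R) − k_R f_R          photochemistry
    f_∞R  = k_M / (k_R + k_M)                  photoequilibrium
    Q_r(λ) = Σ_z I_z κ_zrR Γ_rR dz             rhodopsin quantum catch

with A1-nomogram absorbance templates `Γ` (R515/M495 in R1/2, R545/M505 in
R3–9; α_R = 6 mm⁻¹, α_M = 7.5 mm⁻¹), full tapetal reflection, an
isoquantal white source, and a logistic red screening pigment over
230–420 µm. Because the pigment state filters the light that sets the
pigment state, the equilibrium is found by fixed-point iteration from the
dark-adapted state (or by integrating the ODE system; both paths agree).

The electrophysiology side implements sigmoid intensity–response fitting
(`V = V₀Iⁿ/(Iⁿ + Rⁿ)`), reverse transformation of response amplitudes to
spectral and polarization sensitivities, opponent-unit decomposition under
selective adaptation, cos² polarization fits, and spectral summaries
(peak, FWHM, secondary peaks) — exercised end to end on a seeded synthetic
recording generator with per-species presets.

## Worked example

```r
library(rhabdomR)

cfg <- rhabdom_config()                      # default red ommatidium
eq <- solve_equilibrium_fixed_point(cfg)
eq
#> rhabdom photoequilibrium: converged in 4 iterations (last delta 7.2e-05)
#>   f_R (R545 receptors): 0.518 distal (<230 um), 0.118 basal (350-400 um)

effective_sensitivity(eq)
#> effective sensitivities (whole rhabdom):
#>  receptor peak_nm log10_rel_peak
#>        R1     517          -0.20
#>        R2     517          -0.20
#>        R3     562           0.00
#>        R4     562           0.00
#>        R5     563          -0.42
#>        R6     563          -0.42
#>        R7     563          -0.42
#>        R8     563          -0.42
#>        R9     630          -1.85
```

Most of the rhodopsin survives in the bright distal rhabdom (`f_R ≈ 0.52`)
but is largely converted basally (`≈ 0.12`), where the screening pigment
leaves only red light. R1/2 keep their 515 nm pigment peak (shifted
+2 nm by screening), R3–8 broaden and shift redward, and R9 — behind
420 µm of pigment filtering — peaks at 630 nm, 1.65 log units below R1's
absolute peak sensitivity (1.85 below the most sensitive R3/4).
That is the model's case for R9 as the red opponent unit: a sharp red
receptor that no longer responds in the green.

On the recording side:

```r
cell <- opponent_cell_spec(species = "Argynnis paphia")   # G+R- cell
run <- generate_run(cell, stimulus_protocol("intensity_series",
                                            wavelengths = 525), seed = 7)
fit_intensity_response(run, exclude = c(-1 + 1e-9, 100))
#> sigmoid fit (depolarizing): V0 = 24.95 mV, logR = -2.555, n = 0.852, rmse = 0.309 mV
```

recovering the generative parameters (V₀ = 25, logR = −2.51, n = 0.86) to
within the noise. `analyze_opponent_cell()` runs the whole chain —
both sigmoid fits, opponent decomposition, spectral and polarization
summaries — and `pipeline_reproduce()` wraps model and recovery into one
seeded report.

## The analysis workflow

Numbered drivers under `analysis/` write delimited tables to `results/`:

| script | what it does |
| --- | --- |
| `01_rhabdom_model.R` | model with/without the red pigment: sensitivities, eyeshine, receptor summary |
| `02_synthetic_recordings.R` | benchmark suite of synthetic cells + current-injection reversal demo |
| `03_recover_parameters.R` | full analysis of every synthetic cell; recovered vs generative tables |
| `04_report.R` | end-to-end report: model target checks + per-species recovery |

```sh
Rscript analysis/01_rhabdom_model.R     # and so on
```

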