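# soxdosim

Singlet oxygen dosimetry for Type II photodynamic therapy (PDT) in liquid
phantoms: multispectral singlet oxygen luminescence dosimetry (MSOLD),
the singlet oxygen explicit dosimetry (SOED) kinetic model, their
correlation analysis, and optical-property correction factors — implemented
as a tested R pipeline exercised on synthetic spectrometer data with full
ground truth.

## Who this is for

PDT dosimetry researchers who want to

- decompose near-infrared (1200–1600 nm) spectra into the singlet oxygen
  emission band at 1270 nm, photosensitizer phosphorescence and laser
  background by SVD least squares,
- compute reacted singlet oxygen \[¹O₂\]ᵣₓ from fluence rate, photosensitizer
  concentration and oxygenation with the macroscopic SOED model,
- quantify how linearly the luminescence amplitude tracks the model dose, and
- correct detected luminescence for tissue optical properties (μa, μs′),
  either from a packaged measured correction-factor grid or from a built-in
  Monte Carlo photon transport model.

## The models

**SOED kinetics.** With ground-state photosensitizer \[S₀\] (μM), ground-state
oxygen \[³O₂\] (μM), fluence rate ϕ (mW/cm²), and writing
f = \[³O₂\]/(\[³O₂\]+β), g = σ(\[S₀\]+δ):

    [¹O₂]        = ξ τΔ f ϕ [S₀] / (g + 1)           (quasi-steady concentration)
    d[S₀]/dt     = − ξ f ϕ [S₀] · g/(g + 1)          (photobleaching)
    d[³O₂]/dt    = − ξ f ϕ [S₀] · (g + k₇[A]τΔ)/(g + 1)
    [¹O₂]rx      = ∫ ξ f ϕ [S₀] / (g + 1) dt         (cumulative reacted dose)

Defaults are the in-vitro benzoporphyrin derivative (BPD) parameter set
(ξ = 51×10⁻³ cm² mW⁻¹ s⁻¹, β = 11.9 μM, δ = 33 μM, σ = 1.7×10⁻⁵ μM⁻¹,
τΔ = 9.4 μs, \[A\] = 0). Oxygen can be clamped (the phantom regime, where air
diffusion resupplies the sensed surface layer) or left to evolve.

**MSOLD unmixing.** A measured spectrum y on a wavelength grid is fitted as
y ≈ Σᵢ aᵢ Bᵢ over basis spectra Bᵢ (singlet oxygen band, phosphorescence,
background) by least squares via the singular-value pseudoinverse
(relative cutoff 10⁻¹²), optionally with non-negative amplitudes. The
singlet oxygen amplitude a_o2(t) is the MSOLD dose surrogate; regression of
cumulative MSOLD against cumulative SOED across phantoms yields the
detection scale (counts per μM of singlet oxygen).

**Optical correction.** A packaged 5×5 measured grid of correction factors
over μa ∈ {0.1…1.0} cm⁻¹ and μs′ ∈ {5…40} cm⁻¹ (bilinear interpolation,
reference point μa = 0.3, μs′ = 10), plus a two-stage Monte Carlo photon
transport model (isotropic-scattering similarity, semi-infinite medium,
1.5 mm NA 0.39 collection fiber) that regenerates the signal-vs-(μa, μs′)
behaviour from first principles.

## Worked example

```r
library(soxdosim)

# SOED trajectory for a 6 mg/L BPD phantom, 850 mW/cm2 for 900 s
ph <- phantom_spec(6)
tr <- integrate_soed(ph, irradiation_protocol(), dt_out = 100)
tr
#> <soed_trajectory> 10 time points, 0-900 s
#>   S0: 8.347 -> 7.455e-09 uM; O2rx total: 13264.6 uM; fluence 765 J/cm2

head(as.data.frame(tr)[, c("t_s", "S0_uM", "O2rx_uM", "inst_1O2_uM")], 4)
#>   t_s      S0_uM  O2rx_uM  inst_1O2_uM
#> 1   0 8.34724541     0.00 3.202583e-03
#> 2 100 0.68873948 12049.54 2.642827e-04
#> 3 200 0.06845614 13142.70 2.626822e-05
#> 4 300 0.00691875 13252.27 2.654889e-06
```

The initial instantaneous singlet oxygen concentration is 3.2×10⁻³ μM
(≈ 3.2 nM); as the photosensitizer bleaches, generation collapses and the
cumulative reacted dose saturates at ≈ 13.3 mM. The delivered fluence after
900 s is 765 J/cm².

```r
# five phantoms (2-6 mg/L), 2 % of-peak spectral noise, full pipeline:
# simulate -> unmix -> SOED -> regress cumulative MSOLD on cumulative SOED
cfg <- experiment_config(noise = noise_config("gaussian_scaled",
                                              sigma = 0.02, seed = 1))
rep <- run_experiment(cfg)
rep$cumulative
#> <linfit> y = 499.218 x + -0.396463  (R2 = 0.995347, n = 50)
#>   SE(slope) 4.927, SE(intercept) 0.6233
```

The regression recovers the injected detection scale (κ_detect = 500 counts
per μM) to 0.16 % with R² ≈ 0.995 — the computational content of the claim
that MSOLD linearly tracks the SOED dose.

```r
# correction factor for a medium with mua = 0.5, mus' = 15 cm^-1
cf_lookup(cf_table(), optical_properties(0.5, 15))
#> [1] 0.97
```

A command-line front end over the same functions is installed at
`inst/scripts/soxdosim.R` (subcommands `simulate`, `unmix`, `soed`,
`correlate`, `cf`, `mc-cf`, `run`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","soxdosim.R",package="soxdosim"))')" \
  soed --bpd-mg-per-L 6 --out trajectory.csv
```

## Documentation

See the methods vignette (`vignettes/msold-soed-dosimetry.Rmd`) for the model
assumptions, what the synthetic generator does and does not emulate, the
numerical choices (integrator tolerances, SVD cutoff, Monte Carlo estimators)
and known limitations.
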