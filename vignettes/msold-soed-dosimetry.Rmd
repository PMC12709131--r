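---
title: "Singlet oxygen luminescence and explicit dosimetry: models, assumptions, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Singlet oxygen luminescence and explicit dosimetry: models, assumptions, numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soxdosim)
```

## The problem

Type II photodynamic therapy kills tissue through singlet oxygen (¹O₂)
generated when an excited photosensitizer transfers energy to ground-state
oxygen. Two dosimetry routes exist. *MSOLD* detects the weak ¹O₂
luminescence band at 1270 nm directly inside a 1200–1600 nm spectral window,
where it sits on top of photosensitizer phosphorescence and laser
background. *SOED* never looks at the 1270 nm band: it computes the reacted
singlet oxygen concentration \[¹O₂\]ᵣₓ from quantities that are easier to
measure — fluence rate, photosensitizer concentration, oxygenation — via a
macroscopic kinetic model. The package implements both routes end to end on
synthetic phantom data with recorded ground truth, so that every claim about
their agreement is a computation, not an assertion.

## The kinetic model

`soed_parameters()` carries the in-vitro photophysical constants for the
benzoporphyrin derivative (BPD): ξ (specific oxygen consumption rate,
51×10⁻³ cm² mW⁻¹ s⁻¹), β (oxygen quenching threshold, 11.9 μM), δ
(low-concentration correction, 33 μM), σ (specific photobleaching ratio,
1.7×10⁻⁵ μM⁻¹), τΔ (¹O₂ lifetime, 9.4 μs), and the acceptor term k₇·\[A\]
(zero by default: no azide or substrate in the solvent). With
f = \[³O₂\]/(\[³O₂\]+β) and g = σ(\[S₀\]+δ), the quasi-steady singlet oxygen
concentration is ξ·τΔ·f·ϕ·\[S₀\]/(g+1), photobleaching removes
ground-state photosensitizer at rate ξ·f·ϕ·\[S₀\]·g/(g+1), and the dose
metric \[¹O₂\]ᵣₓ integrates ξ·f·ϕ·\[S₀\]/(g+1) over the protocol. Two
structural properties follow directly from the equations and are enforced by
tests: τΔ times the dose rate equals the instantaneous concentration at every
state, and with \[A\] = 0 the oxygen and photosensitizer equations coincide,
so \[³O₂\] − \[S₀\] is conserved when oxygen evolves.

Two modelling choices deserve comment.

* **Oxygen mode.** In the liquid-phantom regime the measured oxygen
  concentration stays at its initial value (≈ 194 μM) because the sensed
  surface layer re-equilibrates with air faster than PDT consumes oxygen.
  `phantom_spec()` therefore defaults to `oxygen_mode = "clamped"`; the full
  evolving-oxygen system is available for model studies.
* **As-printed kinetics.** The parameter set makes photobleaching fast at
  treatment fluence rates: at 6 mg/L and 850 mW/cm² the bleaching time
  constant is ≈ 35 s, so \[S₀\] is essentially exhausted within the first two
  acquisition intervals and \[¹O₂\]ᵣₓ saturates near 13 mM. Measured
  bleaching curves in this system are far slower and approximately linear.
  The package implements the equations and constants exactly as stated and
  exposes ξ and σ as configuration rather than guessing corrected units; all
  cross-route comparisons are therefore internally consistent whatever the
  bleaching speed. Likewise, the evolving-oxygen equation makes oxygen
  consumption equal photobleaching at \[A\] = 0 — unusual relative to older
  formulations of this model family, but implemented as stated and flagged
  here rather than "fixed".

Unit conversions are explicit: `mgL_to_uM()` (drug mass concentration to
molar, default molecular weight 718.8 g/mol for BPD — the weight is
configurable and all dose outputs can be read against relative
concentration, so no conclusion hinges on it) and `mmHg_to_uM()` (oxygen
partial pressure, 1.295 μM/mmHg).

### Integration

`integrate_soed()` uses `deSolve::lsoda` with relative tolerance 10⁻⁸ and
absolute tolerance 10⁻¹² μM, integrating piecewise between fluence-rate
discontinuities (pause edges) so the solver never steps across a
discontinuity. States are clipped to zero only within the absolute
tolerance; anything more negative raises an error instead of being silently
repaired. The suite checks the adaptive solution against a fixed-step Euler
oracle (dt = 10⁻⁴ s over a 10 s horizon, written out independently in the
test helpers) to 10⁻⁴ relative in all components.

## The synthetic spectrometer

`simulate_series()` is the forward model the analysis assumes: at each
acquisition time the emitted spectrum is an exact linear mixture of three
unit-peak basis shapes plus noise,

* a Gaussian ¹O₂ band (centre 1270 nm, FWHM 20 nm — the band is resolved
  but not parameterised by typical instruments, so both numbers are
  configuration),
* a broad monotone-decaying phosphorescence component (exponential, scale
  200 nm across the window), and
* a laser background concentrated at the short-wavelength edge (exponential,
  scale 30 nm); its true tail shape is instrument-specific and the
  component is synthetic by construction.

The amplitudes follow the kinetics: a_o2(t) = κ_detect·\[¹O₂\](t),
a_phos(t) = κ_phos·ϕ(t)·\[S₀\](t) (phosphorescence proportional to
excitation rate and remaining ground state — the minimal model consistent
with phosphorescence falling as the photosensitizer bleaches), and a
constant background. κ_detect (default 500 counts/μM) and κ_phos (default
2×10⁻⁴ counts per mW cm⁻² μM) are explicit free constants: absolute count
scales depend on fiber, spectrometer and coupling, so only their recovery —
not their values — is meaningful. The defaults make the ¹O₂ band and the
phosphorescence comparable in magnitude at the start of a 6 mg/L run, as
measured spectra show. Noise is additive Gaussian by default (constant sd,
or scaled to the series peak; a Poisson shot-noise option exists); spectra
are acquired in a low-noise long-exposure mode, so a 2 %-of-peak sd is the
realistic operating point used by the end-to-end tests. Each exposure is
treated as an instantaneous sample of the state at the acquisition time —
within-exposure averaging over 5 s is negligible against the 100 s cadence.
A single seeded generator drives each simulation call and the seed is
recorded in the outputs, so every dataset is reproducible byte for byte.

The generator does *not* emulate solvent evaporation, wavelength-dependent
detector response, fiber coupling drift, or optical-property changes during
irradiation. Passing tests therefore demonstrate correctness of the
analysis chain under the stated statistical model, not robustness to those
instrumental effects.

`simulate_quench_pair()` produces the azide-quenching experiment: the
post-quench spectrum keeps a residual fraction r of the ¹O₂ amplitude
(default 0.05 — chemical quenching is never complete), other components
unchanged, so `quench_difference()` isolates (1−r)·a_o2·B_o2 exactly in the
noiseless limit.

## Unmixing

`svd_unmix()` solves the least-squares problem through the singular-value
pseudoinverse with a relative cutoff of 10⁻¹², which reports rather than
amplifies a near-degenerate basis; `basis_matrix()` refuses outright
collinearity at construction. Non-negativity is optional and off by
default: a negative fitted amplitude is diagnostic information about model
mismatch, and clipping it silently would hide that. When requested, the
constraint is imposed by a Lawson–Hanson active-set refinement. The suite
pins the solver to an independent normal-equations solve on random
well-conditioned instances (10⁻⁸ relative) and checks exact recovery,
linearity in the input, and unbiasedness under repeated noise draws.

`fluorescence_unmix()` applies the same solver in the 600–800 nm window with
photosensitizer fluorescence, background, and `n_fourier` cosine/sine pairs
(default one pair — a single slowly varying residual component suffices and
is the conventional choice). Relative photosensitizer concentration is the
amplitude ratio to the pre-treatment acquisition, which cancels the unknown
fluorescence detection scale.

## Correlation analysis

Cumulative quantities are trapezoidal integrals on the acquisition grid
(`cumulative_trapezoid()`; exact for piecewise-linear integrands and the
natural rule for 100 s-cadence data). Both cumulative MSOLD and cumulative
SOED are integrated with the *same* rule on the *same* grid, so their
regression slope estimates κ_detect without quadrature bias even where the
kinetics are fast relative to the cadence; the ODE integrator's own
\[¹O₂\]ᵣₓ is carried alongside in `dose_time_series()` for dose reporting.
"Instantaneous at time t" means the nearest acquisition within half a
cadence step (acquisitions are discrete), with equidistant requests
resolving to the earlier acquisition. Regressions are unweighted ordinary
least squares with an estimated intercept (measured comparisons of this
kind report small nonzero intercepts, so forcing zero would bake in a
conclusion); R² is defined as 0 for a constant response. Experimental
slope values in detector counts are setup-specific, so the meaningful test
is recovery of a known injected κ_detect from noisy data — the suite demands
5 % on the slope, an intercept consistent with zero, and R² > 0.99 at the
2 % noise operating point, and mutual consistency of the instantaneous
slopes at 1, 450 and 900 s.

## Optical-property correction

The packaged grid (`cf_table()`) holds the measured correction factors over
μa ∈ {0.1, 0.3, 0.5, 0.7, 1.0} cm⁻¹ and μs′ ∈ {5, 10, 15, 20, 40} cm⁻¹,
normalised to 1.00 at (μa = 0.3, μs′ = 10). Lookup is exact at nodes and
bilinear between them; outside the hull the query is clamped to the nearest
edge with a warning, because extrapolated corrections are unvalidated. On
load the table is checked to be strictly increasing in μa at every μs′ and
non-increasing in μs′ over the 5–20 cm⁻¹ rows. The measured 40 cm⁻¹ row
breaks μs′-monotonicity by one unit in the last printed digit at μa = 0.7
(1.00 → 1.02); the table is authoritative data, so the monotonicity
guarantee is stated for 5–20 cm⁻¹ only rather than "correcting" the value.

`mc_detected_signal()` is a deliberately simple two-stage photon transport
model whose job is to reproduce the *structure* of the grid from first
principles, not its printed digits:

* similarity relation: isotropic scattering with interaction coefficient
  μt = μa + μs′, absorption as per-interaction weight attenuation μa/μt,
  survival roulette below weight 10⁻⁴ (survivors keep 1-in-10 odds times
  weight 10);
* stage 1 deposits excitation weight on a cylindrical grid
  (dr = dz = 0.05 cm, r ≤ 2 cm, z ≤ 3 cm; deposits outside this volume are
  a negligible fraction and are dropped). Deposited weight density is
  μa × fluence, so the deposited fraction divided by μa measures the fluence
  volume integral that drives ¹O₂ generation for a uniformly distributed
  photosensitizer — this division is what makes the detected signal vanish
  as μa grows;
* stage 2 samples emission sites proportional to deposited weight, emits
  isotropically at the emission wavelength, and detects at a 1.5 mm,
  NA 0.39 flat-cut fiber at the surface: exit within the core radius and
  within asin(NA/n) of the normal, n = 1.33 for an aqueous phantom. The
  emission-wavelength optical pair defaults to the excitation values because
  phantom properties at 1270 nm are rarely characterised; water and lipid
  absorption there differ materially, so the pair is configurable.

Detection through a 1.5 mm fiber is a rare event (≈ 5×10⁻⁴ per emitted
packet), so two estimators are provided: `"analog"` scores the surviving
weight of packets that physically exit inside the acceptance (the direct
transcription of the detection geometry), and `"next_event"` adds at every
vertex the expected unscattered arrival into the acceptance cone
(forced detection). Both estimate the same expectation — the suite checks
their agreement within combined sampling error — but the next-event
standard error is ~5× smaller at equal packet count, so grid scans default
to it. Fixed seeds give identical output; the standard error scales as
1/√n over two decades of packet count. The fiber sits directly on the
surface (the sealing wrap is optically negligible), and the photosensitizer's
own absorption is excluded from μa so the correction isolates the
background optical properties.

Within this model the detected signal falls monotonically with μa and rises
from μs′ = 5 to 20 at fixed μa, reproducing the sign structure of the
measured grid; the μs′ effect is weaker than measured (the similarity model
under-concentrates near-surface fluence relative to forward-peaked
scattering), which is why the acceptance check asserts signs, not values.

## The end-to-end experiment

`run_experiment()` composes the pipeline at the study conditions: phantoms
at 2–6 mg/L, 850 mW/cm² for 900 s, acquisitions every 100 s, simulate →
unmix → integrate → correlate (instantaneous at 1, 450, 900 s, plus pooled
cumulative). Phantom i uses base seed + i − 1, so the whole experiment is
one seed away from reproducible; with an output directory it writes every
intermediate table, the regression JSON and a manifest from which the run
can be replayed exactly (a test does exactly that). Problem sizes
throughout the suite — 256-point spectra, 10 acquisitions, 10²–10⁵ photon
packets, 100–400 Monte Carlo repetitions — are chosen so the full suite
documents the statistics it claims while running in about a minute.

## Known limitations

* The transport model is a similarity approximation: no anisotropic phase
  function, no refractive-index mismatch at the surface beyond the NA
  acceptance cut, homogeneous semi-infinite medium only. It is a trend
  model, not a replacement for a full Monte Carlo with measured phase
  functions.
* The synthetic basis shapes are parametric stand-ins; real basis spectra
  are measured (azide quenching for phosphorescence, direct laser coupling
  for background) and carry their own noise, which the generator does not
  model.
* Spatially resolved dose, oxygen diffusion/perfusion, and microscopic
  triplet-state kinetics are out of scope; oxygen handling is either
  clamped or the printed macroscopic rate equation.
* The fast as-printed bleaching means late-time amplitudes underflow the
  early-time scale; analyses that need late-time instantaneous regressions
  should expect the large standard errors the package reports there.
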