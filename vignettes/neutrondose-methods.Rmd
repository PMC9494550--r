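---
title: "Modelling out-of-field neutron doses in pencil beam scanning proton therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling out-of-field neutron doses in pencil beam scanning proton therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutrondose)
library(dplyr)
```

## The problem

Out-of-field doses to healthy tissue in proton therapy are dominated, away
from the target, by secondary neutrons produced in the patient and the
treatment room. Treatment planning systems do not account for them, yet they
matter for children, pregnant patients and patients with implanted devices.
Around a pencil beam scanning (PBS) delivery, the operational quantity is
the ambient dose equivalent H\*(10), normalised per Gy of absorbed dose in
the target; it depends strongly on where you stand relative to the isocenter
and the beam axis, and on the treatment-plan parameters: field size, proton
range, modulation width of the spread-out Bragg peak (SOBP), and whether a
range shifter is in the beam.

`neutrondose` packages the computational building blocks of this problem:

* lethargy-binned neutron fluence spectra and a parametric spectrum
  generator (`spectra` functions);
* conversion of fluence spectra to H\*(10) and convolution with
  ambient-neutron-monitor energy response functions (`response` functions);
* the two TEPC dose-equivalent algorithms used by area monitors based on
  tissue-equivalent proportional counters (`tepc` functions);
* a k = 1 measurement-uncertainty budget (`uncertainty` functions);
* a per-position multiplicative scaling-law model of H\*(10) versus plan
  parameters, with fitting, prediction and an organ-dose estimator
  (`scaling` functions); and
* a synthetic campaign generator that stands in for Monte Carlo transport
  runs and measurement campaigns (`campaign` functions).

## Neutron spectra and the lethargy grid

Neutron fields in proton therapy rooms span more than eleven decades of
energy, so spectra are tallied on a logarithmic grid with constant bin width
in lethargy, ln(E\_i/E\_{i-1}) = 0.26 by default, from 1e-9 MeV to the
240 MeV transport cutoff. Bins are half-open `[E_lo, E_hi)` and fluence is
stored as the per-bin integral, not a density, which makes band sums and
convolutions plain sums. `per_lethargy()` provides the conventional
plotting view (fluence divided by the bin's lethargy width).

The parametric generator `synthesize_spectrum()` reproduces the
characteristic three-peak structure of such fields:

* a thermal Maxwellian (fluence density proportional to E exp(−E/kT)) at
  kT = 2.585e-8 MeV (0.02585 eV, room temperature);
* a 1/E epithermal tail between 0.5 eV and 10 keV;
* an evaporation Maxwellian at kT = 1 MeV; and
* a Gaussian cascade ("high-energy") peak centred at 0.6 times the maximum
  proton energy with standard deviation 0.15 times that energy.

The shapes are standard textbook forms chosen by this package — measured
and simulated room spectra constrain only the qualitative structure — and
every parameter is settable through `spectrum_shape()`. Each component is
normalised to unit fluence on the grid before being weighted by its
amplitude, so the total fluence equals the amplitude sum exactly and the
generator is homogeneous of degree one in the amplitudes. The generator is
deterministic; all randomness in the package lives in the campaign and TEPC
simulators. The default band boundaries (thermal < 0.5 eV, epithermal
0.5 eV–10 keV, evaporation 10 keV–20 MeV, cascade > 20 MeV) are likewise a
package choice, configurable in `band_fractions()`, because no universal
convention exists.

```{r spectrum}
spec <- synthesize_spectrum(proton_source(c(103, 212), c(1, 2)))
band_fractions(spec)
```

## Fluence to H\*(10) and monitor response convolution

`h10_from_spectrum()` folds a spectrum with tabulated fluence-to-H\*(10)
conversion coefficients (ICRP 74 values shipped as a user-editable CSV;
rows above 201 MeV are an explicitly flagged synthetic extension to the
transport cutoff, never hardcoded). Coefficients and monitor responses are
interpolated log-log between tabulated points — both quantities vary over
decades of energy — with a linear-in-value fallback on segments where a
tabulated response is zero (the high-energy cutoff of conventional
counters), since log-log interpolation is undefined at zero. The
representative energy of a bin is the geometric mean of its edges,
consistent with logarithmic binning.

No real ambient neutron monitor has a flat H\*(10) energy response:
moderated counters under-respond to thermal neutrons, over-respond to
epithermal ones, and conventional (non-extended) counters are nearly blind
above 10–20 MeV, while TEPC-based instruments slightly over-respond to
high-energy neutrons. `expected_monitor_response()` quantifies the net
effect for a given field as the H\*(10)-weighted mean of the response over
the spectrum; `predict_reading()` is the true H\*(10) times that factor.
Outside a monitor's tabulated span but inside its declared valid range the
response extends as a constant at the edge value; evaluating non-zero
fluence outside the valid range is an error, because a silent zero would
fabricate cutoff behaviour that the data do not support. The bundled
response curves are stylized synthetic fixtures (see the file comments);
substitute measured curves via `response_function()` or the YAML registry
for metrological work.

```{r response}
h10 <- h10_from_spectrum(spec)
wendi <- load_monitor("wendi2")
r <- expected_monitor_response(spec, wendi)
c(h10_uSv_per_Gy = h10, expected_response = r, reading = h10 * r)
```

## TEPC dose-equivalent algorithms

Two algorithms are implemented for tissue-equivalent proportional counters.

**Variance method.** Repeated charge integrations (0.1 s intervals by
default) give the mean absorbed dose in the gas,
D = q̄ (W/e) / (M m_det), and the dose-mean lineal energy from the relative
variance of the dose across intervals, ȳ_D = m_det V_rel D̄ / l̄. One
rendering note: the defining relation is sometimes typeset with the mean
chord length as a product; dimensional analysis (energy per unit length)
requires division by l̄, and that is what the package computes. The dose
equivalent is H\* = D̄ (a + b ȳ_D) with a = 0.88 and b = 0.09 µm/keV,
constants appropriate for the high-energy neutron fields of proton therapy
rooms. The photon/neutron dose split inverts the mixing relation
ȳ_D = ȳ_Dγ d_γ + ȳ_Dn (1 − d_γ) with endpoint values 1.4 and 96 keV/µm;
because measurement noise can push ȳ_D past an endpoint, the split clamps
to [0, 1] with a warning instead of failing. The sample variance uses the
unbiased (n − 1) denominator, and a beam-intensity-variance subtraction (as
in variance–covariance implementations) is deliberately not applied: plain
variance is the documented estimator here.

`simulate_tepc_intervals()` generates a compound-Poisson event stream with
lineal energies from a two-component lognormal mixture (photon-like
dose-mean 1.4, neutron-like 96 keV/µm). For a compound Poisson process the
variance estimator converges exactly to the dose-weighted mean lineal
energy E[y²]/E[y] of the event distribution, so the generator can return
analytic truth values and recovery tests are self-contained.

**Single-event method.** From a measured dose distribution in lineal
energy d(y), the dose equivalent is a quality-weighted sum,
H\* = N_low Σ Q(y) d(y) over 0.5–10 keV/µm plus N_high Σ Q(y) d(y) over
10–1024 keV/µm, with calibration factors N_low = 1.1 (compensating the
electronic threshold at 0.5 keV/µm) and N_high = 0.8 (compensating the
proton-edge y-scale calibration). The high-LET component is the
conventional approximation of the neutron H\*(10). Q(y) is not part of the
instrument specification available to us; the package adopts the ICRP 60
quality factor Q(L) with y substituted for LET — standard TEPC practice —
and lets users override it via `hawk_config(quality_function = ...)`. The
d(y) spectrum is stored as absolute dose per bin (Gy) so the sums yield Sv
directly.

## The uncertainty budget

Measured H\*(10) values carry five relative k = 1 components: positioning
(detector placement precision of about 5 cm propagated through a simulated
dose mesh: the detector-volume average at the nominal and six shifted
positions, treated as a uniform distribution between the lowest and highest
value, σ = (max − min)/√12 — the nominal value is included in the min/max
pool), counting statistics (1/√N), calibration (2–6 % depending on the
instrument), target dose (about 2.5 %), and the energy-response deviation
|1 − R| when no spectrum-based correction is applied. When the reading
*is* corrected through `predict_reading()`, the deviation is a correction
rather than an uncertainty and should not be double-counted in the budget.
Components combine in quadrature (`combine_budget()`); the combination rule
for these budgets is not uniquely prescribed anywhere, and root-sum-square
of independent components is the GUM default. Typical configurations land
in the 15–30 % band.

```{r budget}
combine_budget(c(positioning = 0.04, calibration = 0.02, statistical = 0.10,
                 energy_response = 0.25, target_dose = 0.025))
```

## The scaling-law model

Out-of-field H\*(10) per target Gy varies over four orders of magnitude
with position and plan. The model factorises the dependence per position:

H = a0 · (FS/100 cm²) · (1 + c_r (R_eff − 15 cm)) · m(M)/m(10 cm),
  m(M) = 1 + c_m1 M + c_m2 M²

* **Field size** enters exactly linearly in area: the neutron source
  strength is proportional to the number of delivered protons. There is no
  free field-size coefficient; a 3×3 → 30×30 cm² change is a factor of 100.
* **Range** enters linearly with a per-position slope: predictions rise by
  a factor of roughly two to eight over 10–25 cm depending on the position.
* **Modulation** enters quadratically with negative curvature (the effect
  flattens at large widths).
* **Range shifter**: the default mode replaces the range by the effective
  range R_eff = R + WET (3.1 cm water-equivalent thickness), the physical
  first approximation — the protons start with the energy of a deeper plan
  and the extra neutrons are made in the shifter. A `flat_factor` mode
  (multiply by ~2, the empirical average) is provided as the alternative.
* **Air gap** between range shifter and phantom is accepted and ignored:
  no significant effect is observed at these positions, and the model makes
  that explicit (a message notes the deliberate omission).

The reference plan (100 cm², range 15 cm, modulation 10 cm, no shifter) is
fixed so `a0` is an interpretable dose at a central plan. Multiplicative
separability is a modelling choice: the plan parameters have real
interdependencies, which is why coefficients are stored per position and
why cross-position extrapolation should not be trusted beyond a factor of
about three. `glance()` on a fit reports the residual log-scatter so users
can see how much structure the separable law leaves unexplained.

`fit_scaling_model()` fits each position independently by least squares in
log space (so relative, not absolute, errors are minimised across the four
decades of dose), using Levenberg–Marquardt (`minpack.lm::nlsLM`) on
parameters (log a0, c_r, c_m1, c_m2) with fixed starting values
(mean log-dose, 0.05, 0.02, −5e-4) and tight convergence tolerances; rows
are sorted by irradiation id first so the fit is invariant under row
permutation. The design must contain at least two distinct field sizes and
ranges and three distinct modulation widths, otherwise the fit aborts
naming the missing axis. On noise-free synthetic campaigns the generating
coefficients are recovered to numerical precision; at 15 % lognormal noise
with ~70 irradiations the estimates are within ordinary sampling error of
the truth and the reported standard errors are calibrated.

`estimate_organ_dose()` chains the corrections of the model — field-size
ratio, range law between effective ranges, modulation law, inverse-square
distance — and returns each factor separately, so a user can audit an
estimate step by step.

```{r scaling}
fit <- fit_scaling_model(generate_campaign(
  campaign_design(seed = 1, noise_sd = 0.15)
)$measured)
glance(fit)

pos_b <- default_positions() |> dplyr::filter(position == "B")
estimate_organ_dose(
  reference_h10 = 50,
  reference_plan = treatment_plan(100, 20, 5),
  target_plan = treatment_plan(33, 18, 5),
  position = pos_b, target_distance_m = 0.5, model = fit$model
)
```

## The synthetic campaign generator

`generate_campaign()` emulates what a measurement campaign plus transport
simulation would deliver: a factorial plan grid inside the supported domain
(the default design has about 70 irradiations, in line with a realistic
campaign of a few dozen plans), ground-truth doses from a known
`scaling_model`, optional per-position monitor response factors computed by
synthesizing a spectrum per plan (maximum proton energy from the effective
range via the Bragg–Kleeman rule R = 0.0022 E^1.77) and convolving it with
the assigned monitor, and multiplicative lognormal noise with unit mean and
the designed relative sigma (doses are positive, uncertainties relative).
The default truth model's coefficients were chosen once so the synthetic
campaign echoes the documented qualitative behaviour — position ordering
B > F > E ≥ D, range factors 2–8, modulation effect 35–60 % over 3–20 cm,
range-shifter ratio below 2.5 except at position D (which sees the shifter
in line of sight), doses of a few to a few hundred µSv/Gy at 1 m in the
beam direction.

What the generator does *not* emulate: room-scattered neutrons (the reason
measured doses at distant perpendicular positions exceed room-free
simulations), spectral differences between positions, detector dead time,
or interdependencies between plan parameters beyond the multiplicative law
itself. Passing recovery tests therefore demonstrate the correctness of the
estimators under the stated model, not the adequacy of the separable law
for any particular facility.

## Numerical choices and degenerate inputs

* Lethargy grids tolerate floating-point noise when the span is an exact
  multiple of the bin width (a 1e-9 slack inside the `ceiling`).
* `band_fractions()` on an all-zero spectrum returns NaN fractions with a
  warning instead of failing, keeping batch pipelines alive.
* Bin assignment to bands uses the bin's geometric-mean energy, so any full
  partition sums to one exactly.
* Constant charge series have zero variance and hence ȳ_D = 0;
  all-zero series are rejected (the relative variance is undefined).
* CSV dialects are strict: mandatory headers, `#` comments, parse errors
  name the offending line, and floats are serialised at 17 significant
  digits so write/read round trips are value-identical.
* Problem sizes in the test suite (about 70-irradiation campaigns, 1e5
  TEPC intervals, 1000-point property sweeps) were chosen as the smallest
  sizes at which the statistical checks have clear margins.

## Known limitations

* The scaling law is separable and per-position; it cannot represent the
  parameter interdependencies of a real facility, and extrapolation across
  positions or outside the plan domain is order-of-magnitude only.
* The bundled monitor response curves and the >201 MeV conversion
  coefficients are synthetic fixtures.
* Distances and angles for positions A and C are placeholders (`NA`)
  pending user input; the organ-dose estimator refuses to use them.
* Inverse-square extrapolation treats the treatment volume as a point
  source, which degrades close to the phantom.
* The in-phantom problem (organ doses inside the patient) is out of scope.
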