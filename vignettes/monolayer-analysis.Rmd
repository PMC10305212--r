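---
title: "Monolayer isotherm and relaxation analysis: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monolayer isotherm and relaxation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monofilm)
```

## The measurements and their models

A Langmuir trough spreads an amphiphile film at the air–water interface and
compresses it with movable barriers while a Wilhelmy plate records the
surface pressure π (mN/m, typically to ±0.1 mN/m). Two records drive
everything in this package:

* the **compression isotherm** π(A), with A the mean molecular area in
  Å²/molecule, and
* the **constant-area relaxation trace** π(t), recorded after compression
  to an initial pressure π₀ with the barriers then held fixed.

All analyses assume the isotherm is a single compression branch at constant
temperature. `isotherm()` therefore canonicalizes its input: rows are
re-sorted into compression order (area decreasing), duplicate areas are
collapsed by averaging, and small negative pressure readings (sensor noise
around the baseline) are accepted down to −0.5 mN/m in storage but clamped
to 0 for analysis. Hysteresis loops and expansion branches are out of
scope.

### Characteristic parameters

Three quantities summarize an isotherm. The **liftoff area** A_L is where π
first rises detectably above the gaseous-phase baseline; we estimate the
baseline as the median pressure over the largest-area decile of the record
and flag the first sample exceeding it by a configurable threshold
(default 0.5 mN/m — five times a typical sensor accuracy; a smaller value
chases noise, a larger one biases A_L low). The **limiting area** A_∞
extrapolates the steepest stretch of the condensed-phase rise to π = 0; the
"steepest stretch" is the window of consecutive samples (default 5, below
any detected collapse) with the largest |dπ/dA| by local least squares.
The reported value carries the window used as an attribute, since A_∞ is
only defined relative to that choice. The **collapse point** (π_C, A_C) is
the high-pressure kink where the film buckles into the third dimension: we
scan above 30 mN/m for the junction between adjacent windows with the
largest drop in local slope and require the drop to exceed 50% — smooth
records with no such kink return the final point explicitly flagged, which
callers must treat as a censoring indicator, not a measurement.

### Additivity rule and mixing thermodynamics

For an ideally mixed film the limiting area is linear in composition,
A\*_∞ = Σ xᵢ·A_∞,ᵢ (`ideal_limiting_area()`, any number of components; the
common use treats a fixed lipid mixture as one pseudo-component).
`additivity_deviation()` reports experimental − ideal, signed: positive
means looser packing than ideal (repulsion or expulsion of material from
the interface), negative means condensation.

Interactions are quantified by the excess Gibbs energy

G^E(π) = ∫₀^π [A_mix(π′) − Σ xᵢAᵢ(π′)] dπ′,

evaluated by trapezoidal quadrature on a uniform grid (default 200 nodes;
doubling the grid changes smooth cases by <0.1%). The integrand needs areas
*as a function of pressure*, so isotherms are inverted by
`area_at_pressure()`: because measured π(A) can be locally flat or noisy,
the monotone upper envelope along compression is taken before
piecewise-linear inversion — a stated, testable convention rather than an
ad-hoc smoothing. Two boundary conventions matter and are made explicit:

* Below the lowest recorded pressure the area is clamped to the value at
  that floor (real records begin at a noise floor, not at exactly π = 0).
  The clamped subinterval's contribution to the integral is reported
  separately in the `clamp_contribution` attribute so its size is
  auditable; for synthetic grids starting at π = 0 it is exactly zero.
* Above any isotherm's recorded maximum — e.g. past a component's
  collapse — the request raises a range error. Extrapolating a collapsed
  film's area would silently fabricate data.

G^E is computed in the instrument's natural unit (Å²·mN/m per molecule)
and converted to J/mol by the exact factor N_A·10⁻²³ = 6.02214076, because
the Gibbs energy of mixing adds a term that only makes sense in molar
units:

Δ_mixG = G^E + RT·Σ xᵢ ln xᵢ, R = 8.314 J/(mol·K),

with x ln x → 0 for absent components. The default temperature throughout
is 308.15 K (a 35 °C subphase, the usual physiological choice for
pulmonary-surfactant work); it is metadata on every container and
overridable. Negative G^E means net attraction between components,
negative Δ_mixG a mixed film more stable than the separated ones.

### Compressional modulus

Cs⁻¹ = −A·(∂π/∂A)_T characterizes film compressibility; its minimum within
a band marks the LE→LC phase transition and its maximum the stiffest
packing. Finite differences amplify sensor noise to the point of
uselessness, so the derivative comes from a local quadratic fit over a
sliding window (default 7 samples, odd, ≥ 5; windows 5/7/9 agree within 1%
on smooth data, so the default is not load-bearing). The window is carried
on the result. Since areas from a uniform pressure grid are *not*
uniformly spaced, the fit is a windowed least-squares polynomial rather
than a fixed-coefficient convolution filter. The first and last
half-window use one-sided fits and are flagged `endpoint = TRUE`;
`max_modulus()` excludes them by default. The transition search band
defaults to 2–25 mN/m: its lower edge excludes the gaseous region, whose
near-zero modulus would always be the global minimum; a monotone modulus
inside the band returns the band edge flagged `no_interior_minimum`.

### Relaxation kinetics

Constant-area decays are fitted on the normalized scale,
π/π₀ = C + a·e^(−t/τ), by unweighted Levenberg–Marquardt least squares
with τ bounded positive. C is the normalized equilibrium pressure, C + a
the fitted intercept at t = 0 — deliberately *not* constrained to 1, since
measured fits routinely give C + a below 1 when an initial fast process
escapes the sampling. Starting values are taken from the data (C from the
tail, a from the range, τ from the 63%-of-range crossing time), which
makes the τ ≈ 300–1500 s regime converge reliably. r² = 1 − SS_res/SS_tot
is reported as the goodness measure. Traces whose range is below three
times a robust noise estimate (median absolute first difference / √2) are
rejected as degenerate — τ is unidentifiable on a flat trace and a fit
would return an arbitrary number. `recovery_study()` wraps the
generate–fit loop into a bias/RMSE simulation study with a single master
seed.

## The synthetic-data generator as the package's oracle

No public raw π–A or π–t data exist for the systems this methodology is
usually applied to, so validation rests on a generator whose outputs have
known answers. The central design choice is to generate isotherms *from a
prescribed modulus profile* by inverting the modulus definition:

A(π) = A_ref · exp(−∫₀^π dπ′ / Cs⁻¹(π′)),

with the profile given as knots under monotone (Fritsch–Carlson)
interpolation and the integral taken by cumulative trapezoid on a refined
grid (8 substeps per output interval; exact for constant profiles). This
makes every analysis invertible against its own ground truth: the modulus
curve must reproduce the profile (within 2% at interior points), the
transition detector must find a prescribed dip, and the characteristic
parameters follow from the known A(π). Collapse is emulated by switching
to a small post-collapse modulus above π_C, which produces the
near-plateau (rapid area loss at almost constant pressure) that collapse
detection keys on. Mixtures are built as the ideal combination of
component areas plus a prescribed deviation δ(π), so the exact
G^E = ∫₀^π δ dπ′ ships with the object. Relaxation traces come directly
from the single-exponential model. All noise is additive Gaussian on the
pressure channel, flows through one explicit seed, and leaves the caller's
RNG state untouched.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: multiplicative or correlated instrument drift,
barrier-speed dependence, film leakage along the trough edges, replicate
scatter between repeated spreadings, and any chemistry (it knows areas and
pressures, not molecules). Parameter sets in the test fixtures are chosen
to be *typical of published lipid/drug films* (limiting areas of 30–65 Å²,
collapse at 42–54 mN/m, transition dips at 10–15 mN/m, lifetimes of
300–1500 s); they validate the arithmetic at realistic magnitudes and are
not replicas of any measured curve.

## Numerical choices and degenerate inputs

* Interpolation everywhere is piecewise linear (`approx`); monotone
  envelopes guarantee invertibility. Ties in the envelope keep the first
  (largest-area) sample of each pressure maximum.
* Quadrature is trapezoidal; problem sizes in the tests (isotherms of
  ~200–300 samples, 100-replicate recovery studies, 200-node integrals)
  keep the full suite in a few seconds while leaving discretization error
  an order of magnitude below every asserted tolerance.
* Validation is strict at construction time (≥ 10 samples, positive areas,
  the −0.5 mN/m pressure floor, fractions summing to 1 within 10⁻⁹), so
  analysis code never re-checks.
* Degenerate analysis inputs fail loudly with typed messages: pressure
  never lifting off, isotherms truncated below 30 mN/m (no collapse
  reachable), constant relaxation traces, out-of-range pressure queries.
  Batch drivers (`cmd_*`) convert these into per-file error columns and a
  nonzero exit, so one corrupt file cannot void a run.

## Known limitations

* A_∞ and the collapse point depend on window and threshold choices; the
  defaults are sensible for ~0.25 mN/m-resolution records but should be
  revisited for sparse isotherms, and the window is reported with the
  value for that reason.
* The excess-Gibbs integral treats the below-liftoff region by clamping;
  for films with a long gaseous tail the `clamp_contribution` attribute
  should be inspected before interpreting small G^E values.
* The relaxation model is a single exponential; films with two relaxation
  processes will show structured residuals and an r² noticeably below 1,
  and the package deliberately does not auto-select a richer model.
* Replicate combination (averaging repeated isotherms of the same system)
  is left to the caller; the containers carry one record each.
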