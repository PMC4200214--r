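---
title: "Comparative nanoparticle dosimetry: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative nanoparticle dosimetry: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(particledose)
```

`particledose` places in vitro and in vivo nanoparticle response data on a
single dose scale — the particle mass associated with the target cells —
so that effect thresholds measured in culture can be compared with doses
experienced in the intact lung. This vignette is the package's account of
the underlying models: what is assumed, which parameters matter, how the
numerics are controlled, and where the approach stops being trustworthy.

## The dose chain, system by system

### Agglomerate physics

Nanoparticles in protein-containing media do not stay as primary spheres:
they form fractal agglomerates whose hydrodynamic diameter (measured by
dynamic light scattering) is an order of magnitude larger than the primary
size from electron microscopy. The packaged defaults describe a 13 nm
magnetite primary particle (density 5.2 g/cm³) agglomerating to 276 nm in
serum-supplemented RPMI.

Three numbers characterise the agglomerate: the diameter ratio, a fractal
dimension `DF`, and a packing factor `PF`. Sterling's relation gives the
particle count `N = PF·(d_agg/d_p)^DF`; the defaults `DF = 2.1`,
`PF = 0.637` (random close packing) give `N ≈ 390`. The solid volume
fraction `φ = N·(d_p/d_agg)³ ≈ 0.04` then yields the effective density

`ρ_eff = ρ_f + (ρ_p − ρ_f)·φ ≈ 1.17 g/cm³`,

barely above the medium. This is the single most consequential quantity in
the in vitro arm: the settling velocity scales with `ρ_eff − ρ_f`, so an
analysis using the solid density (5.2) would overestimate delivery by
~25-fold. `effective_density()` is guaranteed to lie between the medium and
solid densities and is monotone in `DF`, both enforced by tests.

### In vitro transport

Delivery of suspended agglomerates to the cell monolayer is modelled as
one-dimensional sedimentation–diffusion in the quiescent media column:

`∂C/∂t = D ∂²C/∂x² − V ∂C/∂x`

with `D` from Stokes–Einstein and `V` from Stokes settling, both evaluated
for the *agglomerate* (276 nm, `ρ_eff`), never the primary particle. The
boundary conditions encode the model's two key idealisations:

- **perfect sink at the cell plane** — any particle reaching the bottom is
  "delivered" and does not return. Delivery is thereby separated from
  *association*: the fraction of delivered material that stays with the
  cells through washing is a distinct, fitted quantity (below).
- **zero flux at the free surface** — nothing enters or leaves from above.

For the packaged parameters (`D ≈ 2.2×10⁻¹² m²/s`, `V ≈ 9.6×10⁻⁹ m/s`,
media height 2.6 mm) both mechanisms matter: sedimentation alone would
deliver `Vt/h ≈ 32%` in 24 h, diffusion alone ≈19%; together the solver
delivers ≈40%. Buoyant agglomerates (`ρ_eff < ρ_f`, `V < 0`) are legal
inputs; delivery is then diffusion-dominated.

The suspension is treated as monodisperse (one DLS size class). A
polydisperse extension would superpose independent solves per size class;
it is an extension point, not implemented.

### Cell association

Measured cell-associated mass tracks delivered mass early but falls below
it at later times and higher accumulated doses.
`fit_association_fractions()` always reports the empirical per-timepoint
ratios (measured/delivered) — in the packaged fixture they fall from 93%
at 1–2 h to 67–68% at 8–24 h — and, alongside them, a smooth saturable fit.

No mechanistic form for the saturation is established, so the package uses
the minimal smooth decreasing family, a four-parameter logistic
`f(x) = f_min + (f_max − f_min)/(1 + (x/K)^n)`, fitted by
Levenberg–Marquardt least squares with box constraints
(`0 ≤ f_min, f_max ≤ 1`). Because the per-timepoint ratios are always
reported next to the curve, the chosen form is falsifiable by inspection.
Whether the saturation is driven by time or by cumulative delivered dose is
ambiguous in principle; both covariates are supported (`covariate =
"delivered"`, the default, or `"time"`). Ratios above 1 — possible under
measurement noise — are reported and flagged but clipped to 1 before any
downstream prediction, since the physical bound must hold there.

### In vivo allocation

The in vivo arm does not re-derive airway deposition physics. A
per-generation deposition-fraction table (the output format of multi-path
regional deposition models) is a validated *input*; the measured total
deposited burden (14.5 µg in the packaged configuration) is multiplied
through it. Fractions are renormalised to sum to 1 before allocation — the
packaged regional split (2.8/34/62% across trachea/main bronchus,
bronchiolar and alveolar regions) sums to 0.988 because the three shares
are independently rounded — so the per-generation masses always sum
exactly to the measured total; the renormalisation is reported as a
message, never silent.

Downstream metrics are pure arithmetic, each conservation-checked:
per-cm² dose (mass / generation surface area) and per-macrophage dose. The
macrophage pool (1.25×10⁶ cells, the mouse alveolar population) is
distributed across alveolar generations in proportion to alveoli; the
default scavenging fraction of 1.0 encodes the assumption that deep-lung
macrophages take up essentially all deposited particles, with lower values
(e.g. the literature's 20–80% size-dependent range) supported as a
sensitivity parameter — halving scavenging exactly halves every
per-macrophage dose. Local deposition hot spots at airway bifurcations are
handled by a scalar enhancement factor (default 65, the published CFD
value for ~200 nm particles over a 100 µm patch); the package deliberately
consumes this as a number rather than re-deriving bifurcation flow fields.

### Clearance

Retained-burden time series over the first post-exposure week are fitted
with a zero-order (linear) model `m(t) = m₀ − k·t` by ordinary least
squares, reporting both the absolute rate (µg/h) and the rate normalised
to the fitted intercept (%/day; `k·24/m₀·100`). A first-order exponential
alternative is always fitted alongside and reported via AIC — on the
comparable mass scale, using the lognormal density for the log-linear
fit — but never replaces the linear model as the primary estimate: the
linearity of clearance is a claim the data should be allowed to contradict
through the AIC comparison, not a switch the fitter flips. Negative fitted
rates (apparent growth) are flagged, not clamped; predicted burdens are
clamped at zero with a warning.

### Human extrapolation and band comparison

The human scenario reruns the identical allocation arithmetic with a human
deposition table, a resting adult breathing pattern (tidal volume 625 ml,
12 breaths/min), and eight hours at the occupational limit for iron oxide
(10 mg/m³ as Fe), converted to particle mass by dividing by the iron mass
fraction of magnetite (`3×55.845/231.53 ≈ 0.72`, giving ≈14 mg/m³).
Clearance is deliberately excluded: the scenario reports deposited, not
retained, dose, and no cross-species clearance adjustment is attempted.

The synthesis step, `compare_dose_bands()`, is intentionally elementary:
closed-interval intersection plus a midpoint ratio. The in vitro "effect"
band uses the lowest-observed-effect convention (its lower edge is the
lowest tested dose with a significant response). With the packaged bands
the macrophage comparison (8–35 pg/cell in vitro vs 1–100 pg/cell in vivo)
overlaps and the epithelial comparison (1.2–4 µg/cm² vs 0.009–0.13 µg/cm²)
does not — the package's computational restatement of the finding that
macrophage, but not epithelial, responses concord across systems on a
target-cell dose basis.

## What the synthetic generators emulate

Every measured input has a seeded generator, so the full chain runs and is
tested without any external data:

- `gen_deposition_table()` emulates regional deposition-model output:
  per-generation fractions rolling up *exactly* to a requested regional
  split, surface areas increasing distally, alveoli confined to alveolar
  rows. The mouse-like table targets the 2.8/34/62 split over 22
  generations with region areas 0.4/6/500 cm², landing regional per-area
  doses near the reported ranges (~1 µg/cm² in conducting airways, ~0.02
  µg/cm² alveolar mean). The human-like table expresses fractions relative
  to *inhaled* mass (summing to ≈0.5, a realistic total deposition
  efficiency for a ~70 nm aerosol) over 24 generations with 2×10⁹ alveolar
  macrophages. Both are synthetic stand-ins for real deposition-model
  output: their regional rollups are the constrained, meaningful
  quantities; the per-generation detail is smooth profile plus seeded
  jitter. The human table is additionally constructed so the qualitative
  ordering "human limit-scenario doses ≥ mouse study doses" holds
  region by region, and it is non-authoritative for any quantitative
  human claim.
- `gen_retention_series()` emulates repeated lung-burden measurements:
  a linear decay with multiplicative lognormal noise.
- `gen_invitro_timecourse()` emulates magnetic-particle-detection (MPD)
  cellular dosimetry: solver-delivered mass × prescribed true fraction ×
  lognormal noise.
- `gen_mpd_standard_curve()` / `mpd_calibrate()` / `mpd_quantify()` emulate
  the instrument's calibration: signal proportional to particulate mass,
  inverted through an ordinary least-squares line. Different biological
  matrices are modelled as different gains.

Noise is multiplicative lognormal throughout (doses and signals are
positive by nature), with unit mean and a default relative SD of 5% —
within the spread the instruments in this field report (filter gravimetry
at ~11% RSD; MPD calibration much tighter, default 2%). In noiseless mode
each generator is an exact inverse of its downstream fitting stage, which
the tests exploit as round-trip oracles.

What passing these tests does *not* show: that real cultures are quiescent
columns with perfectly absorbing cells, that real association follows a
logistic, or that real deposition matches the synthetic tables. The tests
establish that the arithmetic chain is self-consistent, conservative, and
able to recover known parameters at realistic noise — the preconditions
for trusting it on real inputs, not a validation against them.

## Numerical choices

**Discretization.** The transport solver is finite-volume with implicit
(backward Euler) time stepping and first-order upwinded advection,
defaults 300 uniform cells and 6 s steps. The scheme is an M-matrix:
unconditionally stable with provably non-negative concentrations
regardless of user parameters. The delivered fraction is computed from the
suspended-mass balance, not a boundary-flux integral, so suspended +
delivered = initial holds to round-off by construction. The absorbing
boundary uses a half-cell gradient; the zero-flux surface carries no
advective term in either flow direction (row sums of the interior columns
vanish exactly — the property that catches sign errors in the boundary
rows, and did catch one during development via the buoyant-particle test).

**Accuracy control.** Three independent cross-checks bound the solver:
the sedimentation-only closed form `min(1, Vt/h)` (agreement within 1%),
the diffusion-only eigenfunction series (within 0.5%; series truncated at
a 10⁻¹² term tolerance), and self-convergence (halving Δx and Δt moves the
24 h delivered fraction by <0.2% at the packaged parameters; the defaults
were chosen to sit inside that band with margin). Requested output times
are sampled at the nearest step, an O(Δt) placement error that is
negligible at 6 s against 1–24 h horizons.

**Fitting.** Ordinary (unweighted) least squares is the default everywhere
because no error model accompanies the packaged means; weighted variants
activate only when per-point dispersions are supplied. The saturable
logistic is fitted by `minpack.lm` with box constraints and a
constant-data fallback (flat fit) for the degenerate all-equal case.
Physical constants are fixed at their exact SI values
(`kB = 1.380649×10⁻²³ J/K`, `g = 9.80665 m/s²`); atomic masses at
conventional values (Fe 55.845, O 15.999).

**Units.** Public interfaces accept the field's mixed units — nm, g/cm³,
µg/ml, mg/m³, Pa·s, K, hours — exactly as practitioners record them, and
convert internally to SI; every returned scalar carries a `unit`
attribute and every table column name carries a unit suffix. The
alternative (SI-only interfaces) invites silent thousand-fold errors when
transcribing published parameters.

**Determinism.** Generators take explicit integer seeds, save and restore
the caller's RNG state, and are bit-reproducible; `run_pipeline()` threads
one seed through every stochastic input and records it, with a
configuration hash, in the provenance block. Reruns with the same seed are
byte-identical, including all written artifacts.

## Problem sizes

The test suite and acceptance script run the solver at its defaults (300
cells, 6 s steps, 24 h horizon; one 2× refined companion run for the
convergence check), 100-replicate recovery studies for the clearance rate,
saturable-fit and calibration-gain parameters, and 25 replicates for the
per-timepoint association recovery. These sizes give stable Monte-Carlo
estimates of the recovery error while keeping a full run in tens of
seconds; they are the package's standing study conditions, not tuning
knobs.

## Design decisions that were genuinely open

- **Association covariate.** Saturation could plausibly follow time or
  cumulative delivered dose; the package defaults to delivered dose (the
  mechanistically natural driver for a saturable process) and exposes the
  choice as an argument rather than deciding it silently.
- **Renormalisation of deposition fractions.** Printed regional splits are
  rounded and rarely sum to 1; conserving the measured total (renormalise,
  then allocate) was chosen over honouring each printed share exactly,
  because mass conservation is the property every downstream metric
  depends on. The ~1% consequences for per-region values are accepted and
  surfaced in the allocation message.
- **Workday scenario concentration.** The iron-adjusted limit is 13.89
  (with the conventionally rounded 0.72 fraction) or 13.82 mg/m³ (exact
  stoichiometry); regulatory statements quote 14. The human scenario uses
  the stated whole-number limit, while the adjustment function itself
  returns the unrounded quotient.
- **Deposition-model physiology vs measured physiology.** Both are kept
  (`mouse_deposition_physiology()` at the nominal 317 breaths/min,
  `mouse_physiology()` at the measured 371), and inhaled mass always uses
  the measured minute volume — mirroring how deposition modelling and
  exposure accounting are actually combined in such studies.

## Known limitations

- The transport model omits dissolution, convection from plate handling,
  particle–particle interactions and well-edge effects; it is a delivery
  model, not an uptake model.
- Association fitting is empirical; the logistic is a description, not a
  mechanism, and extrapolation beyond the fitted dose range is unsafe.
- The deposition tables shipped for testing are synthetic; any real
  analysis must substitute genuine deposition-model output via
  `read_dose_table(..., "deposition")`.
- The human comparison is deposited-dose only; ignoring clearance
  overstates retained human burden by an amount this package does not
  estimate.
- Single lognormal aerosol mode only: `cmd_to_mmd()` is exact for one mode
  and wrong for multimodal spectra, which is why an instrument-derived
  mass median from a full spectrum need not match the converted count
  median.
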