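# particledose

Comparative nanoparticle dosimetry for liquid cell culture and inhalation
exposure systems.

## The problem

In vitro and in vivo nanoparticle toxicity studies are conventionally
reported on incompatible exposure scales — µg/ml of suspension in a culture
well versus mg/m³ of aerosol in an inhalation chamber. Neither is the dose
the cells actually experience, so responses in the two systems cannot be
compared directly, and in vitro assays appear poorly predictive of animal
outcomes. `particledose` implements the target-cell-dosimetry alternative:
compute, for each system, the particle mass that reaches the cells —
per cm² of epithelium and per cell — and compare effect thresholds on that
common scale. The packaged defaults describe a superparamagnetic iron oxide
(SPIO, magnetite) nanoparticle studied both as an aerosol inhaled by mice
and as an agglomerated suspension over mouse lung cell cultures, with an
extrapolation to a human occupational-limit exposure.

The package is aimed at inhalation toxicologists and computational
dosimetrists who need a tested, scriptable version of this dose chain.

## What it computes

**In vitro delivery.** Agglomerated nanoparticles in a culture well settle
and diffuse toward the cell monolayer. The number of primary particles per
agglomerate follows Sterling's relation `N = PF·(d_agg/d_p)^DF`, giving a
solid volume fraction `φ = N·(d_p/d_agg)³` and an effective density
`ρ_eff = ρ_f + (ρ_p − ρ_f)·φ`. Transport to the cells is the 1-D
convection–diffusion problem

```
∂C/∂t = D ∂²C/∂x² − V ∂C/∂x,   D = kB·T/(3π·μ·d),   V = g·d²(ρ_eff − ρ_f)/(18μ)
```

on the media column, with an absorbing cell plane and a zero-flux surface,
solved by an implicit finite-volume scheme whose delivered fraction is
conservative by construction. A measured cellular-dose time course then
yields the **association fraction** (cell-associated / delivered mass),
per time point and as a fitted saturable logistic.

**In vivo allocation.** The measured total deposited lung burden is
allocated across airway generations by a deposition-model fraction table,
yielding per-cm² tissue doses and — distributing 1.25×10⁶ alveolar
macrophages in proportion to alveoli — per-macrophage doses, with optional
scavenging-fraction and bifurcation hot-spot adjustments. Retained-burden
time series are fitted with single-phase linear (zero-order) clearance.

**Cross-system synthesis.** Effective-dose intervals from each system are
compared as closed bands on the same metric, and the whole chain is rerun
for a human breathing pattern at the iron-content-adjusted occupational
exposure limit (10 mg/m³ as Fe → ≈14 mg/m³ as particle).

All "measured" inputs have seeded synthetic generators with the statistical
structure of the real instruments, so every stage is testable end to end
without external data.

## Worked example

```r
library(particledose)
res <- run_pipeline(seed = 1)   # packaged SPIO defaults, synthetic inputs
print(res)
```

```
<pipeline_result>
  delivered fraction at 24 h: 0.403
  association fractions: 0.9, 0.94, 0.85, 0.72, 0.69
  clearance: 0.050 ug/h (8.2 %/day)
  adjusted occupational limit: 13.8 mg/m^3
  band comparison:
# A tibble: 2 × 9
  metric   system_a context_a      system_b context_b     overlaps overlap_lower
  <chr>    <chr>    <chr>          <chr>    <chr>         <lgl>            <dbl>
1 per_cell in_vitro BMM            in_vivo  alveolar mac… TRUE                 8
2 per_area in_vitro C10 epithelial in_vivo  alveolar tis… FALSE               NA
```

Reading the output: the transport model delivers 40% of the suspended 10
µg/ml dose to the cell plane by 24 h; the association fractions recovered
from the noisy synthetic time course decline from ~0.93 early to ~0.68 at
8–24 h; the clearance fit returns the 0.05 µg/h (≈8 %/day) rate the
synthetic retention series was built around. The band comparison is the
headline science: macrophage effective doses in vitro (8–35 pg/cell) fall
inside the in vivo alveolar macrophage range (1–100 pg/cell), while
epithelial effective doses in vitro (1.2–4 µg/cm²) do not overlap the
alveolar tissue doses in vivo (0.009–0.13 µg/cm²).

The regional rollup of the mouse dose chain:

```r
res$mouse_rollup
#   region                mass_ug  area_cm2  surface_dose  macrophage_dose_pg
# 1 trachea_main_bronchus   0.411       0.4        1.03                 NA
# 2 bronchiolar             4.99        6          0.832                NA
# 3 alveolar                9.10      500          0.0182               7.28
```

i.e. 62% of the 14.5 µg burden lands in the alveolar region, a mean of
~7.3 pg per macrophage.

## Layout

- `R/` — particle/agglomerate physics, transport solver, association and
  clearance fitting, regional dosimetry, extrapolation, synthetic
  generators, schema-validated IO and the pipeline driver
- `vignettes/comparative-dosimetry.Rmd` — the methods vignette: models,
  assumptions, parameter choices, numerical details, limitations
- `inst/extdata/config-default.yaml` — the packaged study configuration
- `tests/testthat/` — unit, property and acceptance tests
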