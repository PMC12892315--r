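---
title: "Methods: stochastic techno-economic assessment of a grass-silage biorefinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic techno-economic assessment of a grass-silage biorefinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silagetea)
```

## The model

`silagetea` evaluates the economics of converting ensiled grass into
food-grade protein concentrate by mechanochemical-assisted extraction
(twin-screw extrusion with sodium carbonate, solid–liquid separation and
membrane concentration), with two plant configurations:

* **scenario 1** — protein extraction only; the lignocellulosic residue is
  sold to external anaerobic digestion (AD) operators, and lignin is sold
  separately;
* **scenario 2** — the residual carbohydrate fraction is additionally
  hydrolysed and fermented by an oleaginous yeast
  (*Metschnikowia pulcherrima*) into a lipid-rich biomass coproduct.

The pipeline is: mass balance → factored costing → discounted cash flow →
Monte Carlo uncertainty propagation → sensitivity sweeps → spatial
feedstock-supply simulation.

### Mass balance

The design basis processes 33,333 t/y of silage. Product streams are
yield-proportional: protein output is `capacity × e/100` where `e` is the
protein extraction efficiency in g protein per 100 g silage (default 15,
a theoretical-maximum recovery for high-quality forage, giving the
5,000 t/y base-case protein target); lipid-rich yeast is 10 g/100 g
(scenario 2 only, 3,333 t/y) and lignin 12 g/100 g (4,000 t/y). The AD
solids stream defaults to the stated mass-balance value of 28,500 t/y and
is kept as stated rather than recomputed as capacity minus protein (the two
differ by ~170 t/y, presumably from reagent and moisture bookkeeping in the
underlying balance); it rescales proportionally with capacity.

`e` is the model's single protein-yield knob. The extraction-stage stream
split (22 wt% of biomass solubilised, 52% of total protein recovered in the
liquid phase, 60 wt% dry-basis concentrate purity) is carried as a
diagnostic description of the front end in `extraction_streams()`; it does
not override `e` in revenue calculations, because the assessment is
deliberately yield-driven rather than species- or process-step-specific.

### Factored costing

Total capital investment is a Garrett-style factored estimate:

    TCI = [ Σᵢ purchase_costᵢ ] × (1 + Σ direct factors) × (1 + indirect)

with additive direct factors (piping 0.45, electrical 0.20, foundations
0.15, utilities 0.25, installation 0.45) followed by a multiplicative
indirect factor (0.25, engineering and contingency). Additive-direct /
multiplicative-indirect is the conventional ordering for this family of
estimates; the `factor_set()` object makes it auditable and swappable.
Contingency sits in the indirect factor. AD infrastructure is excluded from
TCI, and digestate handling from TPC, since residual solids are valorised
through third-party facilities.

Total production cost is a sum of operating items, `usage × unit price`,
across categories raw material, utility, labour, maintenance, membrane
replacement (a recurring operating cost, not periodic capital) and fixed
charges.

### Valuation

Net present value over a `T = 25` year life at discount rate `r = 0.08`
(base year 2024):

    NPV = Σ_{t=1..T} (R_t − C_t) / (1+r)^t − TCI

Revenues and costs are constant across operating years (no ramp-up, no
salvage value) and TCI is spent at time zero. The unit production cost of
protein is `(annualised TCI + TPC) / annual protein output`; annualisation
uses the capital recovery factor `r(1+r)^T/((1+r)^T−1)` by default, with a
straight-line alternative (`TCI/T`), since the annualisation convention
behind published unit costs of this kind is often unstated. At `r = 0` the
CRF reduces to straight line. The break-even protein price solves
`NPV = 0` by bisection (relative tolerance 1e-8); with coproduct revenues
excluded and CRF annualisation it equals the unit cost analytically, which
the test suite asserts numerically.

### Monte Carlo engine

All uncertain parameters are sampled independently (n = 10,000 draws by
default) — independence is the standard early-stage assumption when
correlation data are unavailable. Distribution kinds:

* protein price: normal, mean £15/kg, sd chosen so the central 95% interval
  spans £10–20/kg (`sd_from_ci(5, 0.95)` = 2.551, using the two-sided
  normal quantile 1.959964);
* lipid-rich biomass: truncated normal, mean £3/kg on [2, 5], sd 0.75
  (= (upper − lower)/4, a deliberate choice since only mean and bounds are
  given);
* residual AD solids £0.06–0.10/kg and wet silage feedstock £0.10–0.18/kg:
  uniform, the least-informative distribution on a bounded range;
* lignin: truncated normal, mean £0.10/kg on [0.05, 0.15] — a minor revenue
  stream chosen at AD-gate-fee scale;
* cost parameters: truncated normals with symmetric bounds, keeping draws
  physical (non-negative) and the truncated median at the mean.

Truncated-normal sampling under the default `"resample"` policy uses the
inverse-CDF transform, which draws from exactly the truncated law — the
same distribution a rejection/resampling loop converges to — without
probability-mass atoms at the bounds; a `"clip"` policy (clamping normal
draws) is provided for comparison and does create atoms. Summaries use the
linear-interpolation quantile convention (`stats::quantile` type 7) for the
median and the 5th/95th percentiles bounding the 90% interval. ENPV is the
arithmetic mean of the NPV draws. All randomness flows from a single seed;
results are reproducible byte-for-byte given (seed, n, parameter set).

### Sensitivity analyses

One-at-a-time tornado analysis fixes every input at its distribution median
and evaluates ENPV at the low and high bound of one parameter at a time
(truncation bounds, or the central 95% interval for the untruncated normal
protein price; 6–12% for the discount rate). The bound evaluations are
deterministic by default — the ENPV of a degenerate evaluation is its
NPV — with an optional mode that reruns the full Monte Carlo per bound.
Because NPV is affine in any single price, the tornado swing for a price
equals `stream mass × 1000 × annuity factor × range width`, an analytic
identity the tests assert to 1e-6 relative.

The extraction sweep recomputes the protein stream over `e = 0..15` in
multiproduct or protein-only revenue mode; `marginal_gains()` converts ENPV
changes per efficiency band into £M per g gains (rounded to one decimal, to
match how such tables are conventionally printed) with their mean and
sample standard deviation across bands. The scale sweep spans 1,000 to
100,000 t protein/y: capital scales with the capacity ratio to an exponent
(default 0.6, the six-tenths rule — no scaling law is prescribed by the
source analysis, so the exponent is an explicit knob), raw-material,
utility and membrane-replacement items scale linearly, and labour,
maintenance and fixed items follow the capital exponent, reflecting their
sublinear growth with plant size.

### Spatial feedstock supply

Silage is sourced radially from the annulus between a 5 km nonharvestable
exclusion radius `r0` and the outer radius `R` that balances supply with
demand, `R = sqrt(r0² + demand/(yield × land_fraction × 100π))`
(1 km² = 100 ha). The mean haul is the area-weighted mean radial distance
`(2/3)(R³−r0³)/(R²−r0²)` — the natural continuum limit of hauling from
throughout the catchment, cross-checked in the tests against a 10⁶-point
uniform-annulus sampler — multiplied by a road tortuosity factor of 1.45.
Delivered cost per wet tonne (25% dry matter) is the farmgate
opportunity-cost price plus `transport rate × haul × 2` (return trips:
empty backhaul priced at the loaded-leg rate, making the doubling
explicit). Dry-matter conversion multiplies by `to_dm/from_dm` (×3.8 from
25% to 95% DM), preserving cost per tonne of dry matter exactly.

Two region profiles ship with the package: `region_livestock()`
(pasture-dominated, e.g. Wales — yield ~25 wet t/ha, 30% land fraction,
farmgate mean £35/t) and `region_arable()` (e.g. East of England — higher
yield, smaller available fraction, higher opportunity cost, farmgate mean
£41.3/t). Transport rates (~£1/t/km loaded leg) are not published for this
system; the profiles are *calibrated* so simulated means land near observed
regional delivered-cost levels, and are documented as calibration rather
than reproduction. The supply simulation uses n = 1,000 draws.

## The fixture generator

The itemised vendor-quote cost tables behind the published medians are not
publicly available, so `generate_fixture()` is the authoritative stand-in:
a synthetic but fully explicit parametrisation. It builds a plausible
equipment list (extruder, mill, hydrocyclone, membrane unit, spray dryer,
tanks, CIP for the baseline; hydrolysis reactors, fermenters, lipid
recovery, expanded utilities for scenario 2) and operating items, jitters
the means reproducibly under the seed, then rescales them so the
deterministic (all-medians) evaluation hits the calibration anchors
exactly: TCI £4.8M / £13.5M and TPC £14M/y / £16M/y for scenarios 1/2. The
silage feedstock price (£100–180/t wet) and the product price book are
fixed inputs and are never rescaled. `noise_level` (default 0.1, sd as a
fraction of the mean, truncated at ±2.5 sd) controls parametric
uncertainty; 0 collapses every distribution to a point.

What the fixture does **not** emulate: the real line-item granularity,
inter-item cost correlations, vendor-quote skewness, or the particular
spreads that produced the published TCI/TPC confidence intervals. Passing
the calibration tests therefore shows that the *machinery* (costing,
sampling, valuation) is correct and that the fixture medians match their
anchors — not that the item-level cost structure matches the unpublished
one. Absolute NPV levels and ENPV swings inherit this caveat and are
checked directionally only (scenario 2 > scenario 1, all-positive NPV);
notably, published NPV medians for this system imply coproduct economics
that cannot be reconstructed from the printed prices alone.

## Numerical choices

* Quantiles: linear interpolation (type 7), stated because "90% CI" alone
  does not pin a convention.
* Truncated-normal medians: exact inverse-CDF formula (equals the mean for
  symmetric bounds).
* Bisection: relative tolerance 1e-8, bracket expanded by doubling until
  the sign changes; no sign change raises an error rather than returning a
  boundary value.
* Degenerate Monte Carlo (all point distributions) reproduces the
  deterministic pipeline *exactly* (bit-identical), enforced by summing
  elementwise products in the same order in both code paths.
* Empirical CDF exports use the `i/n` convention.
* Config round-trips: YAML written at 15 significant digits so
  `load_config(save_config(x))` is the identity to ~1e-12.

## Problem sizes

Scenario simulations use n = 10,000 draws and the supply model n = 1,000
draws, matching the study design; the root-n convergence property test
uses 100 replicate seeds at n = 150 vs n = 1,350, and the haul-distance
oracle uses 10⁶ uniform annulus points. All sizes run comfortably on a
single CPU.

## Known limitations

* No correlation structure between parameters; no IRR, payback, tax or
  depreciation scheduling; no working capital.
* No per-item equipment cost-capacity curves — scale effects enter only
  through the global exponent in `scale_sweep()`.
* The catchment is isotropic; real road networks enter only through the
  tortuosity multiplier, and no raster land cover or multi-depot siting is
  modelled.
* AD is an external off-take: no reactor sizing, biogas yield or digestate
  economics.
* Prices are static distributions, not market forecasts.
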