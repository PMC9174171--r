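---
title: "An abiotic phosphorus-cycle box model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An abiotic phosphorus-cycle box model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoscycle)
```

## The model

`phoscycle` integrates the phosphorus (P) content of eight planetary
reservoirs — atmosphere (ATM), oceans, continental crust (CC), oceanic crust
(OC), marine sediments (MS), upper mantle (UM), lower mantle (LM) and an
inert core — over the 4.5 Ga since the Moon-forming impact, with every
biological flux deliberately absent. The point of the exercise is a null
model: where does abiotic geodynamics alone put phosphorus, and how large a
correction does life have to be to reconcile that picture with the modern
inventories?

Each reservoir is spatially homogeneous and exchanges P through directed,
parameterized fluxes (kg P yr⁻¹):

* **Extraterrestrial delivery.** `F(t) = F0 + (F1 − F0) e^(−t/τ)` with
  `F1 = 2×10⁸` kg/yr at accretion, `F0 = 2×10⁵` kg/yr today and
  `τ = 150` Ma, split between emergent land (to CC) and the ocean in
  proportion to surface area.
* **Riverine erosion (CC → ocean).** `α · A_land(t) · ρ_cc · c_CC`, with
  `α = 2.2×10⁻⁴` m/yr and `c_CC` the CC P concentration. At the modern
  state this is ~7.7×10¹⁰ kg/yr.
* **Aeolian transport (CC → ATM).** The modern calibration of
  27 kg P km⁻² yr⁻¹ scaled by land area and relative CC P concentration
  (4.0×10⁹ kg/yr today); a `β`-based rock-erosion mode is selectable.
* **Sea spray (ocean → ATM).** Dissolved molarity times a constant
  mobilized-seawater volume, calibrated to 3.3×10⁸ kg/yr for a saturated
  modern ocean.
* **Subduction and accretion.** `F_ms→um = (1−ε)·M_MS/τ_sub`,
  `F_ms→cc = ε·M_MS/τ_sub`, `F_oc→um = M_OC/τ_sub` with `ε = 0.30` and
  `τ_sub = 100` Ma.
* **Volcanism.** Arc (UM→CC), mid-ocean-ridge (UM→OC) and hotspot
  (LM→crust) channels, each `s(t)·V·ρ_mantle·c_source·E` with modern
  volumes 2.75 / 20 / 2.25 km³ yr⁻¹, enrichment factors 5 / 4.6 / 4.6 and a
  volcanic activity scale `s(t) = 1 + (f−1)e^(−t/τ_volc)`, `f = 3`.
  The hotspot total is split between CC and OC by the emergent-area
  fraction.
* **Hydrothermal drawdown (ocean → OC).** `H0·e^(−t/τ_hydro)`, clamped so
  the ocean is never overdrawn within a step.
* **Mantle mixing (UM ↔ LM).** Balanced rock exchange: a rock mass
  `r(t)·rock_LM` crosses the boundary each way per year carrying P at the
  source concentration, with `r(t)` relaxing from 3×10⁻⁸ yr⁻¹ (vigorous
  early convection) to 1×10⁻⁸ yr⁻¹ today.

Two reservoirs are **saturation-capped "switchboards"**: the atmosphere
(2.8×10⁷ kg) and the ocean (2.2 µM of apatite-buffered phosphate,
≈ 9.5×10¹³ kg in 1.4×10²¹ L). After every Euler update, atmospheric excess
rains out (3.2/4.6 to the continents, 1.4/4.6 to the oceans) and oceanic
excess precipitates (90% to MS, 10% to OC, the near-shore vs open-ocean
split of erosionally derived P). Because inputs always exceed the caps,
these two reservoirs pin at saturation almost immediately and simply route
mass — which is why percent deviations from modern values are reported only
for the five solid-Earth reservoirs.

Emergent land grows piecewise-linearly from 1% of the modern area to 2/3 at
1.5 Ga and to the modern 1.48×10⁸ km² at 4.5 Ga; an exponentially relaxing
alternative (`builtin:campbell_growth`) is provided and both curves agree
at the endpoints.

## Integration and numerical choices

* **Explicit Euler, `dt = 5,000 yr × 9×10⁵` steps.** The stiff, fast
  reservoirs (atmosphere, ocean) are handled by the cap mechanism rather
  than the step size; all remaining dynamics have timescales of 10⁷ yr and
  longer, so halving `dt` changes final reservoirs by less than 10⁻⁶ %
  (asserted at 0.5% in the acceptance suite).
* **Caps are enforced after the flux update**, not before, so within a step
  a capped reservoir can transiently hold excess that is then routed
  downstream. This "instantaneous overflow" reading matches reservoirs that
  must rapidly shed anything above saturation.
* **Outflow limiter.** If a reservoir's combined outflows would overdraw it
  within a step, all of its outflows are scaled by a common factor. This
  preserves flux ratios, guarantees non-negativity, and conserves mass
  exactly; it only ever engages during the first steps after an extreme
  random seeding.
* **Conservation audit.** The state carries cumulative extraterrestrial
  input, and every stored snapshot checks
  |Σ non-core masses − seed − cumulative ET| / seed ≤ 10⁻⁶ (observed at
  ~10⁻¹⁴, i.e. pure round-off).
* **Drivers are evaluated once per step** at the step's start time, so no
  intra-step drift between coupled channels is possible.
* **Performance.** The production loop is compiled (Rcpp); a reference R
  step (`step_state()`) implements the identical arithmetic and the test
  suite asserts their agreement to round-off over hundreds of steps. A full
  4.5 Ga run takes ~0.07 s, a 50-member ensemble ~3 s.
* **Snapshot decimation** defaults to every 100 steps (0.5 Ma) for single
  runs and 900 steps (4.5 Ma) for ensemble convergence diagnostics.

## Random seeding and ensembles

A run starts from an initial bulk-silicate-Earth (BSE) P mass of
8.4×10²⁰ kg — 10% of the chondritic planetary inventory, the remainder
being sequestered in the core — distributed as: atmosphere and ocean at
their caps, CC and MS at 100 kg (to avoid numerical degeneracy), and the
residual split over LM, UM and OC by symmetric-Dirichlet (uniform simplex)
weights. Alternative core sequestration fractions (85/95/97%) rescale the
seed (`builtin:core85` etc.). Per-run seeds derive deterministically from a
master seed; identical master seeds give bit-identical ensembles.

`convergence_time()` defines "apparent steady state" as the earliest time
after which a series stays within ±2% of its final value — a deliberate
operationalization, since steady states here drift slowly with the decaying
drivers. The across-run spread statistic is `100·(max−min)/mean` of final
values.

## What the generator emulates — and what it does not

The randomized seeding emulates ignorance of the post-core-formation P
distribution, *not* measurement error: every run conserves the same BSE
total, and all runs collapse onto a common trajectory once mantle mixing
homogenizes concentrations (tens of Ma). A green seed-independence test
therefore establishes insensitivity to initial allocation, and nothing
else: it cannot validate the flux parameterizations themselves, which are
point estimates with order-of-magnitude literature uncertainties explored
only through the one-at-a-time sweeps. The model also omits, by design:
the bombardment spike (its cumulative 2×10¹⁵–2×10¹⁶ kg is small against
surface inventories and is handled as back-of-envelope arithmetic via
`cumulative_constant_flux()`), sea-level cycling, P redox speciation,
distinct CC lithologies, and every biological flux.

## Design decisions in the open parts of the specification

Several elements of the published description are qualitative; the package
fixes them as follows, as its own design choices:

* **Mantle mixing as balanced rock exchange.** A naive symmetric law
  `mix_up = r·M_LM, mix_down = r·M_UM` equilibrates *P masses*, which would
  drive LM and UM to equal P content (−32%/+85% against modern estimates).
  Convective exchange moves *rock*, which carries P at the source
  concentration; the balanced-rock-exchange law equilibrates
  *concentrations* (both layers at ~200 ppm), reproducing the near-modern
  mantle steady states the model is known for. The up-flux is numerically
  identical to `r(t)·M_LM` in both readings.
* **Erosion references the modern CC rock mass** (`cc_rock_growth = FALSE`
  by default). If the CC rock inventory is assumed to grow in lockstep with
  emergent area, land area cancels out of the erosion law entirely and
  erosional output becomes independent of continental growth — deleting the
  mechanism by which growing emergent area drives the late decline of CC P.
  Referencing concentration to the (constant) modern rock mass keeps
  average CC P content roughly stationary, consistent with the observation
  that crustal P concentrations have varied little over geological time.
  The growth-scaled variant remains available (`cc_rock_growth = TRUE`),
  and `cc_rock_mass()` itself always reports the growth-scaled inventory.
* **Decay constants for volcanism and mixing.** The exponential-relaxation
  family is reused for every secular driver. `tau_volc` defaults to 0.5 Ga:
  with slower decay (e.g. 1.5 Ga) the volcanic driver is still ~10% above
  its asymptote at 4.5 Ga and the crustal reservoirs drift until ~4 Ga,
  incompatible with crustal convergence on a 1–2.5 Ga timescale.
  `tau_mix` and `tau_hydro` default to 1.5 Ga (secular mantle cooling);
  `H0 = 10⁹` kg/yr is an exposed placeholder — the hydrothermal magnitude
  is stated as a form, not a number, in the source literature.
* **Riverine calibration.** Two printed calibrations conflict by two orders
  of magnitude: the physical-erosion law (`α`, giving ~7.7×10¹⁰ kg P/yr
  today) and a literature total of ~4.1×10¹² kg/yr. The latter would
  overfill the marine-sediment steady state by orders of magnitude
  (0.9 × 4.1×10¹² × 100 Ma ≈ 3.7×10²⁰ kg ≫ 4×10¹⁸ kg); the `α` law is the
  operative flux and the literature figure is retained only as reported
  arithmetic (`areal_flux_total(2.8e4, 1.48e8)`).
* **"~40% emergent CC area"** is ambiguous in the source (40% of CC area
  emergent vs a 40% areal endpoint); the growth curve instead targets the
  unambiguous modern subaerial area, 1.48×10⁸ km², and the endpoint is a
  parameter.
* **Configuration format** is JSON (the one structured text format with a
  first-class parser in the dependency set); builtin scenarios ship as
  reviewable data files under `inst/extdata/configs/`. Progress logging is
  per run (seed, final CC, conservation residual) rather than per
  10⁴ steps — at ~0.07 s per run, finer granularity is noise.
* **Ensemble statistics** report the ensemble mean (per-run finals are
  retained); the published deviations do not say whether they are means or
  a representative run.

## Known limitations

The headline limitation is quantitative: under the printed flux laws and
parameter values, the converged CC and MS reservoirs fall well short of
their modern estimates (the acceptance suite computes the exact figures;
the CC deviation is recomputed as acceptance target `t10`, at about −80%
against a published +42%). The published steady-state deviations are, in
fact, mutually inconsistent with the published flux equations: a CC
overshoot of +42% requires ~10¹¹ kg/yr of riverine erosion, whose 90%
marine-sediment share at a 100 Ma turnover implies an MS *overshoot* of
~+150%, not the published −10%. The reference implementation evidently
differs from its printed description in a way the description does not
record; this package implements the printed equations. The mantle
reservoirs — which dominate the planetary budget and are the strongest
observational constraint — do land within a few percent of modern
estimates, as published, and every qualitative feature (switchboard
saturation, mantle-before-crust convergence ordering, CC rise-peak-decline,
sweep resiliences) is reproduced.

Everything else is inherited from the box-model idealization: single
oxidation state, globally averaged lithology, no local enrichment
mechanisms, literature point estimates for fluxes whose true uncertainties
span orders of magnitude.

## Reproducing the analyses

```r
# main ensemble (Fig.-2-style analysis)
ens <- run_ensemble(50, p_params(), p_structure(), master_seed = 1)
tidy(ens)       # per-reservoir deviations, convergence times, spreads
autoplot(ens)   # ensemble trajectories

# sensitivity sweep
sw <- run_sweep(
  sweep_spec("ocean_sat_conc", logspace(2.2e-10, 2.2e-6, 5)),
  p_params(), p_structure()
)
max_relative_change(sw, "MS")
```

The same computations are scripted: `scripts/acceptance.R` recomputes the
acceptance targets, and the CLI (`inst/cli/phoscycle.R`) exposes `run` and
`sweep` subcommands for shell use.
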