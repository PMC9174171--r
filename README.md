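# phoscycle

A global box model of **abiotic phosphorus cycling** on rocky planets.
Phosphorus is a structural requirement of every known biochemistry and a
limiting nutrient in the modern oceans, so how geodynamics alone
distributes P between planetary reservoirs — before or without life — is a
first-order question for the origin of life and for planetary
habitability. `phoscycle` is a null model for that question: it integrates
the P content of eight reservoirs (atmosphere, oceans, continental crust
CC, oceanic crust OC, marine sediments MS, upper mantle UM, lower mantle
LM, and an inert core) over the 4.5 Ga of Earth history, with every
biological flux switched off, and asks how far the abiotic steady state
lands from today's biologically reworked inventories.

## The model

Reservoirs exchange P (kg yr⁻¹) through parameterized directed fluxes:

* extraterrestrial delivery `F(t) = F₀ + (F₁ − F₀)e^(−t/τ)`
  (2×10⁵ … 2×10⁸ kg yr⁻¹, τ = 150 Ma), split land/ocean by surface area;
* riverine erosion `α·A_land(t)·ρ_cc·c_CC` (α = 2.2×10⁻⁴ m yr⁻¹) and
  aeolian dust export (27 kg P km⁻² yr⁻¹ modern calibration), both scaling
  with CC P concentration;
* sea spray (3.3×10⁸ kg yr⁻¹ from a saturated modern ocean);
* subduction / accretion `F_ms→um = (1−ε)M_MS/τ_sub`,
  `F_ms→cc = ε·M_MS/τ_sub`, `F_oc→um = M_OC/τ_sub`
  (ε = 0.30, τ_sub = 100 Ma);
* arc / mid-ocean-ridge / hotspot volcanism
  `s(t)·V·ρ_mantle·c_source·E`, with the activity scale `s(t)` decaying
  from 3× to modern;
* hydrothermal ocean→OC drawdown, exponentially decaying;
* mantle mixing as balanced rock exchange at rate 1–3 ×10⁻⁸ yr⁻¹.

The atmosphere (2.8×10⁷ kg) and ocean (2.2 µM apatite solubility ceiling,
≈9.5×10¹³ kg) are saturation-capped "switchboards": any excess is routed
onward within the step (rain-out 3.2/4.6 to land; ocean overflow 90% to MS,
10% to OC). Integration is explicit Euler, 9×10⁵ steps of 5,000 yr, in
compiled code, with a mass-conservation audit at every snapshot
(residual ≤ 10⁻⁶; observed ~10⁻¹⁴). Runs start from a randomized
distribution of the 8.4×10²⁰ kg bulk-silicate-Earth P seed and converge to
seed-independent steady states; `run_ensemble()` quantifies that, and
`run_sweep()` does one-at-a-time parameter sensitivity. See the methods
vignette (`vignettes/phosphorus-cycle-model.Rmd`) for every design
decision and known limitation.

## Worked example

```r
library(phoscycle)

ens <- run_ensemble(50, p_params(), p_structure(), master_seed = 1)
tidy(ens)
#> # A tibble: 7 × 6
#>   reservoir mean_final_kg spread_pct convergence_yr modern_kg deviation_pct
#>   <chr>             <dbl>      <dbl>          <dbl>     <dbl>         <dbl>
#> 1 ATM             2.8 e 7 0                       0   2.8 e 7         NA
#> 2 OCEAN           9.54e13 0               130500000   9.30e13         NA
#> 3 CC              2.85e18 0.00144        4302000000   1.4 e19        -79.6
#> 4 OC              6.80e18 0.0000393      2628000000   7.20e18         -5.57
#> 5 MS              1.40e18 0.00216        2731500000   4   e18        -64.9
#> 6 UM              2.23e20 0.00000679      330750000   2.20e20          1.17
#> 7 LM              6.06e20 0.00000970      375750000   6   e20          1.07
```

Reading this: across 50 random initial seedings, every run converges to
the same steady state (`spread_pct` ≤ 0.002%). The atmosphere and ocean pin
at their saturation caps. The mantle reservoirs — 98% of the
bulk-silicate budget — land within ~1% of their modern estimates, with the
mantle settling in ~0.35 Ga and the crustal reservoirs over ~2.7 Ga
(`glance(ens)` summarizes both). The abiotic crustal steady states fall
short of modern inventories (CC −80%, MS −65%): the gap between this null
model and the modern Earth is the model's measure of how strongly
(biologically enhanced) weathering, erosion and sediment accretion rework
surface phosphorus. `autoplot(ens)` draws the ensemble trajectories;
single runs (`run_simulation()`), sweeps (`run_sweep()`) and JSON/CSV
writers round out the toolkit, and a thin CLI lives at
`inst/cli/phoscycle.R`:

```sh
Rscript inst/cli/phoscycle.R run --config builtin:main --seeds 50 \
    --master-seed 1 --out out/
Rscript inst/cli/phoscycle.R sweep --config builtin:main --param epsilon \
    --values 0,0.25,0.5,0.75,1.0 --out out/
```

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, (t10) the percent deviation of the converged continental-crust P
reservoir from its modern estimate for the main configuration, averaged
over a 50-member randomly seeded ensemble, and (t12) the maximum percent
change of the final MS and OC reservoirs when the oceanic saturation
concentration is swept over four orders of magnitude:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
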