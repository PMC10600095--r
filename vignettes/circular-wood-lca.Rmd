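---
title: "Modelling the greenhouse-gas consequences of circular wood use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the greenhouse-gas consequences of circular wood use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circwood)
```

## The question the model answers

A national forestry value chain can mitigate climate change in several,
partly competing ways: wood products store carbon while in service,
displace fossil-intensive materials and fuels, and — when recovered wood
is recycled back into products — reduce the demand for virgin harvest,
leaving more carbon standing in forests. `circwood` implements a dynamic,
consequential life-cycle model of these mechanisms for a softwood value
chain at national scale, run annually from 2022 to 2050 at a constant
harvest (9.5 Mt green tonnes/yr by default).

Four wood-use scenarios are compared:

* **bau** — today's flows: most harvest to sawmills and wood panels, with
  recovered waste wood already cascaded into particleboard and energy;
* **cascading** — more sawnwood and less panel production from virgin
  wood;
* **circular** — recovered waste MDF is recycled into recycled MDF,
  cutting virgin panel feedstock and diverting spared roundwood to
  sawmills;
* **cascading_circular** — both changes combined.

The accounting is *consequential*: only changes relative to the `bau`
reference carry credits or burdens. Total product consumption is held
constant — when domestic production shifts, import volumes adjust to
balance — and the baseline import burden, forest-ecosystem sequestration
and HWP storage of `bau` itself are all set to zero by convention.

## Emission components, scopes and sign convention

Each annual result row is a `(year, component, scope, value_tco2e)`
entry. Emissions are positive, removals and avoided emissions negative.
The components are: four domestic process components (forestry
operations, sawmilling, wood panel production, woodfuel production),
carrying Scopes 1–3; the change in domestic HWP carbon storage
(`scope = "storage"`); and three avoided-emission components
(`scope = "4"`): import change, reduced harvest, and product
substitution.

The two net series are defined as

* `net_s13` = Scopes 1–3 **plus** the HWP storage change, and
* `net_s14` = `net_s13` + the three Scope-4 components, exactly.

The HWP storage change sits inside the `net_s13` boundary because it is
a biogenic carbon flux of the domestic value chain itself, not an
avoided emission elsewhere; this is also what makes it possible for the
circular scenarios' annual `net_s13` to cross zero and turn the domestic
chain into a net sink while process emissions remain positive — the
behaviour the fixture reproduces (see `fx_results` in the test suite and
`scripts/acceptance.R`).

## Wood flows and import rebalancing

A scenario is a mass-balanced directed network (green tonnes/yr) over a
fixed node registry: source nodes (forest gate, recovered waste wood,
recovered waste MDF), process nodes (sawmill, particleboard, MDF and
recycled-MDF mills, the woodfuel chain), terminal product nodes (one per
HWP category) and explicit loss nodes. `build_scenario_flows()` rejects
unknown nodes, negative quantities and any process-node imbalance beyond
`1e-6` relative — the operation is pure arithmetic, so only rounding
error is tolerated. `scale_to_harvest()` is linear and balance
preserving.

`derive_import_deltas()` applies the constant-supply rule per category
(recycled MDF counts toward the MDF group, since it is a drop-in
substitute). Woodfuel is the exception: only a fraction
`woodfuel_replacement` (default 0.4) of any domestic woodfuel shortfall
is replaced by imports, so circular scenarios show a *real* net
reduction in woodfuel consumption. The value is not published for the
system the model emulates; 0.4 was fixed once as a mid-range assumption
and is configurable.

A consequence worth noting: in the cascading scenario domestic panel
production falls, so panel imports *rise*, and because panels carry the
highest embodied burden per unit product the import-change term is
positive, almost exactly offsetting the domestic Scope 1–3 savings.
Cascading's modest net gain therefore comes from HWP storage — the model
reproduces this mechanism rather than assuming cascading is always
beneficial.

## Process emissions and decarbonisation

Emission factors are pre-characterised kg CO2e (GWP100) per green tonne
of process throughput; there is no per-gas bookkeeping because only the
CO2e-expressed impact category is evaluated. Panel mills carry their
resin burden as separate Scope 3 rows tagged `resins`, keeping the resin
share inspectable; in the shipped inventory it is ~40 % of the panel
burden, and panels are ~61 % of the `bau` Scope 1–3 total.

Each factor row carries a decarbonisation sector. The schedule is a step
function per sector with steps at 2030, 2040 and 2050; multipliers are 1
before the first step and must be non-increasing. The shipped schedule is
a calibration assumption (electricity fastest, resins and minerals
lagging, nothing reaching zero by 2050, so the `bau` chain only
approaches net zero beyond the study horizon). Import-change emissions
use per-category embodied factors set equal to the domestic chain burden
per unit product (the equivalence assumption), plus transport, and
decarbonise on the same schedule — exporting countries are assumed to
decarbonise at the domestic rate.

## HWP carbon pools

Products enter per-category first-order pools (the IPCC simple-decay
form) with decay constant `k = ln 2 / half_life`:

```
next = exp(-k) * stock + (1 - exp(-k))/k * inflow
release = stock + inflow - next
```

The recurrence is exactly conservative (asserted at machine precision in
the tests) and `1 - exp(-k)` is computed via `expm1`, so the
infinite-half-life limit (`release -> 0`) is numerically clean. Woodfuel
has half-life 0: immediate release, which is also why wood combustion
adds no separate biogenic CO2 term elsewhere. Default half-lives
(sawnwood 35 y; panels 25 y; fencing, pallets, poles and other 20 y) are
configurable assumptions in the spirit of commodity-class defaults with
category-level modification (pallets and fencing are heavily reused and
repaired in service); the exact decay factors used by the study the
model emulates are not published.

The storage credit is the annualised average stock gain versus `bau`:
the gain trajectory is averaged over the 50 years following the first
divergence and divided by the window, then converted by 44/12 and
reported as a constant annual entry from the implementation year. The
division by the window makes the credit an annual rate whose cumulative
total over the window is of the same order as the carbon physically
gained; production beyond 2050 is held at its 2050 value to close the
window. `bau` versus itself gives exactly zero.

## Forest carbon

The forest layer is deliberately transparent rather than a re-creation
of a full forest-sector carbon budget model, whose parameterisation is
not reproducible from published text. It consists of:

* **Yield curves**: Chapman–Richards sigmoids normalised so the maximum
  mean annual increment equals the yield class (the UK productivity
  index). Shape defaults (`k = 0.035`, `p = 2.5`) put MAI culmination
  near age 45–50, typical of upland conifers. Tabulated curves can be
  supplied instead (`yield_curve_from_points()`), with linear
  interpolation and flat extrapolation beyond the last point.
* **Carbon conversion**: a single volume-to-carbon product
  (`tc_per_m3 = 0.28`, i.e. basic density 0.35 odt/m3 x carbon fraction
  0.5 x whole-tree expansion factor 1.6).
* **Soil / dead organic matter**: one first-order pool (half-life 30 y)
  fed by a biomass turnover fraction (0.015/yr) and clearfell residues
  (30 % of felled biomass), initialised at the baseline steady state for
  estates.

The avoided-harvest credit follows the study design it emulates: any
positive recycled-MDF volume shifts a 710,000-ha spruce estate (a proxy
for the displaced non-domestic harvest) from a 50- to a 54-year
rotation. The estate is simulated as an age-class vector starting fully
regulated; extending the rotation pauses clearfelling for four years and
permanently raises the mean standing stock. The credit is the 28-year
average carbon gain annualised (divided by the window) — the same
annualisation as the HWP credit. The rotation shift is fixed rather than
solved from the harvest reduction, so the credit is a step function of
recycled volume; the implied long-run harvest reduction is reported
alongside so users can supply their own mapping. A closed-form check
(the regulated-estate mean stock as the age-class average of the yield
curve) agrees with the cohort simulation to 0.1 %.

The afforestation programme (20,000 ha/yr, 2023–2050, half pure
commercial conifer at YC 16 and half an even conifer:broadleaf mixture
whose aggregate yield class is the weighted mean of its species) is a
superposition of unharvested cohorts; felling starts beyond the horizon.
The model starts planting in 2023 (the later of the two start years the
emulated study quotes); it is configurable. Its cumulative sequestration
by 2050 (~−71 Mt CO2e under these defaults) is smaller than CBM-derived
published figures for comparable programmes — the simple one-pool
soil/DOM model and conservative yield assumptions are the likely cause,
and the value is reported as computed, not tuned.

## Substitution credits

Wood energy displaces delivered natural-gas energy
(`9000 MJ/t x 0.066 kg CO2e/MJ` by default); construction sawnwood is
translated to timber-frame wall area (`0.0175 m3` timber per m2 at
density 500 kg/m3 at 20 % moisture) displacing a single-skin 140-mm
concrete-block wall (10 kg CO2e/m2, composed offline from block, sand
and cement factors). Both credits are multiplied by the decarbonisation
multiplier of the displaced sector, so they fade as the counterfactual
decarbonises — while the biogenic storage credits do not, which is why
circular scenarios' advantage is resilient to industrial
decarbonisation. Credits are computed on *consumption*, which import
rebalancing holds constant across scenarios: identical in `bau` and
`cascading`, and reduced only via the real woodfuel consumption drop in
circular scenarios. Timber-wall manufacturing emissions are not netted
inside the credit; they live in the Scope 1–3 inventory.

## Scenario orchestration

`run_scenario()` uses the `bau` table before the implementation year and
the scenario table from it onward ("year 5" and "year 10" map to 2027
and 2032, with study year 1 = 2023 — an interpretation, configurable).
The two credits are constant annualised entries from the implementation
year; process, import and substitution terms are year-resolved. The
cumulative series accrues from 2023 on a 2022 baseline, i.e. 28 annual
steps. Afforestation combines additively with any scenario — no
interaction is modelled, and the tests assert the sum is exact.

Comparisons (`compare_scenarios()`) refuse a non-negative reference net
with an explicit error instead of returning `NaN`, since "X % larger
reduction" is undefined when the reference is not a reduction.

## What the synthetic data do and do not establish

`make_paper_like_fixture()` is the package's deterministic study-like
bundle. Its flow shares, factors and schedule are *calibrations* chosen
once to reproduce the qualitative structure of the system it emulates —
panel-dominated Scope 1–3 with a large resin share, fuel and
construction credits of similar magnitude, recycling displacing virgin
panel feedstock, `bau` 2035 net Scope 1–4 on the order of −2 Mt CO2e —
not measurements. Passing tests on this fixture demonstrate that the
*mechanisms* (mass balance, conservation, ordering of scenarios,
net-zero crossing, delay dominance) behave correctly; they do not
validate the magnitudes against real inventories. Real applications
should supply their own inventories through the CSV interfaces
(`write_fixture()` / `load_fixture()` document the layout).

`random_instance(list(seed = s))` produces structurally valid but
randomised bundles (multiplicative flow jitter rebalanced by
construction, log-uniform factors in [1, 300] kg/gt, half-lives in
[2, 50] y, random yield class) for property-based testing; it is a pure
function of the seed and leaves the global RNG stream untouched.

## Numerical choices and degenerate inputs

* Node-balance tolerance `1e-6` relative to the harvest (arithmetic
  only); empty flow tables are vacuously balanced.
* Pool recurrences use `expm1`; conservation is exact by construction
  (release is the balance residual), so round-off cannot leak carbon.
* Half-life 0 is the immediate-release convention, not a division by
  zero; negative stocks/inflows are rejected.
* Zero recycled volume, zero planting rate and empty specs all return
  exact zeros rather than degenerate simulations.
* Yield curves are clamped flat beyond the last tabulated age
  (senescence and volume decline are not modelled).

## Problem sizes

The shipped analyses are small by design: 29 annual steps per scenario,
~80-year pool windows, a 710,000-ha estate as a single age-class vector,
and 56 afforestation cohorts. A full four-scenario run takes a few
seconds; the complete test suite, including a 100-instance random sweep,
runs in under a minute on one core.

## Known limitations

* Flow topologies are limited to the fixed node registry; intra-year
  dynamics, stochastic wood supply and price-mediated displacement
  elasticities are out of scope.
* The forest layer is a one-pool soil model with a fixed
  volume-to-carbon product, not a multi-pool budget model; absolute
  forest-carbon magnitudes are correspondingly coarse.
* Substitution covers gas energy and concrete walls only; steel,
  plastics and building-lifecycle effects are not modelled.
* No uncertainty propagation on emission factors; factors are point
  values.
* Landfill methane, imported-HWP storage, pulpwood and bioenergy with
  carbon capture are excluded by scope.

## A worked run

```{r run, eval = FALSE}
fx <- make_paper_like_fixture()
res <- run_all_scenarios(fx, implementation_year = 2027)
res$circular
compare_scenarios(res$bau, res$circular, "s14_pct_larger_reduction", 2035)
af <- afforestation_series(fx$afforestation, years = 2022:2050)
combine_afforestation(res$cascading_circular, af)
plot_trajectories(res, "cumulative_s14")
```
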