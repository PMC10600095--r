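# circwood

Dynamic consequential life-cycle assessment (LCA) of circular wood use in
a national forestry value chain.

## What it is for

Forestry value chains mitigate climate change through several coupled
mechanisms: harvested wood products (HWP) store carbon while in service,
wood displaces fossil-intensive fuels and materials, and recycling
recovered wood reduces demand for virgin harvest, leaving more carbon in
forests. Whether re-organising the chain — more *cascading* use (sawnwood
before panels before energy) or more *circular* use (recycling waste MDF
into recycled MDF) — actually reduces net greenhouse-gas emissions is a
system-level question: import volumes rebalance, substitution credits
fade as linked industries decarbonise, and storage credits accrue slowly.

`circwood` is for LCA practitioners and forest-sector analysts who want a
tested, fully inspectable model of that system. It runs four wood-use
scenarios (`bau`, `cascading`, `circular`, `cascading_circular`)
annually over 2022–2050 at a constant national harvest (9.5 Mt green
tonnes/yr by default) and produces annual and cumulative Scope 1–4 CO2e
trajectories per value-chain component.

## The model in brief

* **Wood flows** — each scenario is a mass-balanced flow network
  (green t/yr) from forest gate through mills to product and loss nodes;
  validation enforces per-node balance to 1e-6 relative. Total product
  supply is held constant across scenarios by import rebalancing
  (consequential convention), except a real net reduction in woodfuel
  consumption in circular scenarios.
* **Process emissions** — Scope 1–3 factors (kg CO2e per green tonne of
  throughput) per process and sector, under a stepwise decadal
  decarbonisation schedule (steps 2030/2040/2050); panel resin burdens
  are separate Scope 3 rows.
* **HWP carbon** — per-category first-order pools, the IPCC simple-decay
  form `S(t+1) = e^(-k) S(t) + (1-e^(-k))/k * I(t)`, `k = ln2 /
  half-life`, exactly conservative; fuelwood is immediate release. The
  storage credit is the annualised 50-year average stock gain versus
  `bau`, x 44/12, negative for gains.
* **Forest carbon** — Chapman–Richards yield curves normalised so max
  mean annual increment equals the yield class; a regulated 710,000-ha
  estate shifting from a 50- to a 54-year rotation when MDF recycling
  displaces virgin harvest (credit = annualised 28-year average estate
  carbon gain); an afforestation programme (20,000 ha/yr, 2023–2050) as
  a superposition of unharvested cohorts.
* **Substitution** — wood energy displaces delivered natural-gas energy;
  construction timber, converted to timber-frame wall area (0.0175 m3
  per m2), displaces a 140-mm concrete-block wall. Credits shrink with
  the displaced sector's decarbonisation multiplier.

Sign convention: emissions positive, removals/avoided negative. The
annual net excluding avoided emissions (`net_s13`) includes the domestic
HWP storage change (a biogenic flux inside the boundary);
`net_s14 = net_s13 +` avoided components (imports, reduced harvest,
substitution), exactly.

A deterministic study-like input bundle (`make_paper_like_fixture()`,
also shipped as editable CSVs under `inst/extdata/`) and a seeded random
generator (`random_instance()`) make every stage testable without any
download. The fixture is a documented calibration, not observed data.

## Worked example

```r
library(circwood)
fx  <- make_paper_like_fixture()
res <- run_all_scenarios(fx, implementation_year = 2027)  # "year 5"
res$circular
#> <scenario_result> 'circular' 2022-2050 (implemented 2027)
#>   net Scope 1-3 2050: -8.111e+04 t CO2e/yr
#>   net Scope 1-4 2050: -2.356e+06 t CO2e/yr
#>   cumulative net Scope 1-4 by 2050: -8.204e+07 t CO2e
```

The circular chain's annual Scope 1–3 net (process emissions plus HWP
storage change) crosses zero by 2050 — the chain becomes a net sink —
while `bau` stays positive. Net Scope 1–4 is strongly negative
throughout: avoided emissions outweigh the chain's own burden.

```r
compare_scenarios(res$bau, res$circular, "s14_pct_larger_reduction", 2035)
#> [1] 72.92468
```

In 2035 the circular scenario's net reduction is ~73 % larger than
business-as-usual's.

```r
af <- afforestation_series(fx$afforestation, years = 2022:2050)
tail(combine_afforestation(res$cascading_circular, af), 3)
#>    year scenario_cumulative afforestation_cumulative combined_cumulative
#> 1  2048          -77823129.               -57131562.         -134954691.
#> 2  2049          -80724813.               -63721082.         -144445895.
#> 3  2050          -83154022.               -70729482.         -153883504.
```

Circular wood use mitigates early and steadily; afforestation builds
late and accelerates; combined they reach ~−154 Mt CO2e cumulative by
2050 under the fixture's assumptions. `plot_trajectories(res,
"cumulative_s14")` draws the trajectories.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/circwood.R run --scenario circular --implement-year 2027 --out out/
Rscript inst/cli/circwood.R compare --a bau --b circular \
    --metric s14_pct_larger_reduction --year 2035
Rscript inst/cli/circwood.R synth --out my_inputs/   # editable CSV bundle
```

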