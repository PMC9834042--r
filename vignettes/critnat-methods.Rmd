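---
title: "Methods: models, parameters and design choices in critnat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in critnat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critnat)
```

## The model in one paragraph

`critnat` maps *critical natural assets*: the smallest set of natural and
semi-natural pixels that jointly maintain a proportional target (by
default 90%) of the current level of each of 14 nature's contributions to
people (NCP). Each NCP is a non-negative per-pixel surface, zero off its
natural-asset mask, valued where the *providing* habitat sits (value is
attributed back from farms, shorelines and downstream populations to the
habitat that generates the service). The prioritization is a minimum-area
set multicover: select pixels \(s(x) \in \{0,1\}\) minimizing
\(\sum_x s(x)\) subject to \(\sum_x v_i(x)\,s(x) \ge t_i \sum_x v_i(x)\)
for every NCP \(i\). Because targets are proportional, layer scaling
cancels and layers enter constraints un-normalized. Local NCP are solved
within each planning region (per realm: land and EEZ separately), global
NCP (carbon, moisture) in one pooled instance.

## The fourteen NCP surfaces

Thirteen "local" layers represent twelve local NCP (timber contributes
two spatially mutually exclusive layers), plus two global layers:

| layer | formula (simplified form implemented here) | units |
|---|---|---|
| nitrogen_retention | load intercepted along D8 paths × people downstream | load × persons |
| sediment_retention | same, erosion loads and sediment efficiencies | load × persons |
| pollination | production × dependency × habitat sufficiency, split equally over in-range habitat | t/yr |
| fodder | min(forage supply, livestock demand), max-rescaled | 0–1 index |
| commercial_timber | sustainable supply where travel ≤ 360 min to a >50,000-person centre and slope < 70% | 0–1 index |
| domestic_timber | min(supply, per-capita demand within 10 km) on commercially inaccessible cells | 0–1 index |
| fuelwood | min(supply, rural-poor demand within 10 km) | 0–1 index |
| flood_regulation | mean(wetland, canopy, soil storage) × people downstream | index × persons |
| nature_access | people within 1 h (or 6 h) least-cost travel | persons |
| riverine_fish | basin regression predictions rescaled to reported regional totals, spread over freshwater habitat | t/km²/yr |
| marine_fish | exogenous catch surface masked to marine habitat | t/km²/yr |
| reef_tourism | exogenous expenditure deciles masked to marine habitat | decile |
| coastal_protection | (exposure without − with habitat) × people < 10 m within protective distance, credited to habitat | index × persons |
| carbon_storage | stock × disturbance-vulnerability fraction × area (global) | tC |
| moisture_recycling | ET × vegetation fraction delivered onto rain-fed productive land by a conservative transport kernel (global) | ET-equivalent |

The retention, coastal and pollination models are deliberate
simplifications standing in for full process engines (nutrient/sediment
delivery-ratio models, wave-exposure models, pollinator foraging models):
they keep the *stated* structure — interception along the flow path,
value projected from the shoreline back to habitat, sufficiency within
flight range — while replacing internal physics with transparent,
testable arithmetic.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| cell size | 2 | km | working resolution of the analysis |
| headline target | 0.9 | — | the "critical" operating point; curve computed 5%–100% in 5% steps |
| access budget | 60 (360) | min | 1 h default, 6 h sensitivity switch |
| commercial travel cutoff | 360 | min | inclusive (≤); minutes beyond exclude |
| centre threshold | 50,000 | persons | strict (>) on summed urban components |
| slope cutoff | 70 | % | strict (<): exactly 70% is excluded |
| gathering/demand radius | 10 | km | fuelwood and domestic-timber demand, floodplain buffer |
| coastal elevation cutoff | 10 | m | strict (<) for the exposed strip |
| pollinator flight range | 2 | cells (~4 km) | configurable |
| protective distance | 2 | cells | coastal value attribution radius |
| floodplain accumulation threshold | 25 | cells | proxy channel definition |
| retention efficiencies | per class, 0.2–0.8 | — | wetlands > forest > grassland |
| log-linear endpoints | 1,000 / 250,000 | km² | common representation-target convention; the published constants live in supplementary material, so they are configuration here |
| minimum-area floor | 10 | km² | Red-List-style persistence surrogate |

All of these are surfaced as named keys on `run_config()` and echoed into
the YAML written with each run.

## What the synthetic generator emulates — and what it does not

`make_landscape()` reproduces the *statistical* features the models rely
on: one master seed fans out to named RNG sub-streams per raster (adding
a raster never perturbs the others); land cover is a smoothed random
field thresholded to configured proportions (default 60% natural) with
urban placed on population maxima and cropland biased toward settlement
(the adjacency pollination needs); population is a mixture of Gaussian
city kernels (default 120,000 persons, comfortably above the timber
centre threshold) over a lognormal rural background; elevation is a
distance-to-coast ramp plus ridged noise, pit-filled so every land cell
drains; species ranges are connected blobs log-uniform in area from
4 km² to a quarter of the land.

It does **not** emulate: the real class legend or demographic structure,
bathymetry beyond a realm mask, mode-specific transport networks,
anisotropic travel, teleconnected trade, or the magnitudes of any real
place. A green test therefore establishes that the *algorithms* are
correct and the *contracts* hold (non-negativity, mass conservation,
feasibility, determinism, monotonicity) — it does not validate the
published global percentages, which depend on the real data stack and are
out of scope by design.

## Numerical choices

* **Pit filling** is priority-flood with an epsilon increment
  (`eps = 1e-6` m): raised cells sit `eps` above their spill neighbour,
  which removes pits *and* resolves flats deterministically; already
  draining surfaces return unchanged. In degenerate one-row grids only
  the line ends are edge outlets, so a `[1, 0, 1]` line fills its centre
  to `1 + eps`.
* **D8 ties** break by the fixed code order E, SE, S, SW, W, NW, N, NE;
  gradients use drop/distance with diagonal distance `cell × √2`. A land
  descent is preferred over a marine outlet; cells with no lower land
  neighbour that touch marine water or the map edge are outlets.
* **Travel costs** use the mid-point rule (mean of the two cells'
  friction × step length), making times exactly symmetric; fields are
  exact label-setting shortest paths, and `population_within()` is
  computed by truncated expansions from populated cells, which by
  symmetry must (and in tests does) equal the per-target definition.
* **Exact solver**: instances ≤ 20 cells are solved by exhaustive
  subset-sum enumeration with a lexicographic smallest-index tie-break
  among optima; 21–200 cells by branch-and-bound (admissible per-
  constraint prefix-sum bound, greedy incumbent). There is no MIP library
  in the target environment, so the solver is authored here; its area is
  verified against an independent chunked-enumeration oracle on hundreds
  of random instances. Beyond the cap, the documented policy switches to
  the greedy surrogate, and *every* emitted solution — exact or greedy —
  is re-audited for feasibility directly from the layer rasters.
* **Greedy score**: `Σ_i min(v_i(x), deficit_i) / T_i`, ties to the
  lowest cell index; feasible by construction for targets ≤ 1, with the
  standard multicover logarithmic approximation bound checked in tests.
* **Constraint hygiene**: NCP with zero total over an instance impose no
  constraint and are dropped; region-less (overlapping-claim) cells are
  excluded from national instances; feasibility tolerances are
  `1e-9 · max(1, need)`.
* **Nesting is not assumed**: the solution at 90% need not contain the
  solution at 50%; curves report areas, not nested sets.

## Design choices where the source was open

* **People downstream excludes the pixel's own residents** (they live
  *on*, not *downstream of*, the asset), matching the separation of
  beneficiaries from residents; an `include_self` switch exists.
* **Flood storage index** is the unweighted mean of the three components
  — no weights are published.
* **Pollination credits** split equally among in-range habitat cells; the
  attribution rule is stated only as "mapped back to habitat".
* **Index rescaling** (fodder, timber, fuelwood) is max-normalization;
  percentile normalization would also satisfy "re-scaled 0–1" but is less
  transparent.
* **Fodder demand** is compared at cell scale, not aggregated scale.
* **Timber/fuelwood demand caps** use `min(supply, demand)` symmetry with
  fodder; "supply × demand cap" is otherwise dimensionally ambiguous.
* **Accounting for the 12-vs-13 layer question**: commercial and domestic
  timber each enter the optimization as separate constraints since they
  serve disjoint beneficiaries and are spatially exclusive.
* **Realms**: each country's land and EEZ are solved separately (their
  areas are reported separately); layers with realm `both` (coastal
  protection) participate in both solves restricted to cells of the
  matching realm.
* **Riverine fish**: basins are D8 catchments (≥ 5 cells); only basins
  containing freshwater habitat enter the regional rescale, so the layer
  total equals the reported total over placeable regions; the pipeline
  skips (with a warning) regions whose catch cannot be placed, while the
  operation errors by default.
* **Beneficiary union** is person-level: someone in several benefit areas
  counts once — the "intersection to avoid double-counting" logic.
* **Unachievable species targets** are flagged when the target area
  exceeds the mapped habitat itself (possible when the recorded range is
  larger than the mapped AOH); the `min(1, ·)` cap makes the minimum-area
  rule achievable by construction on our overlays.

## Known limitations

* The greedy surrogate carries no optimality certificate, and dropping a
  constraint is guaranteed not to increase area only for the exact
  solver; the drop-one monotonicity check therefore runs on
  exact-solvable fixture sizes.
* The moisture kernel is a conservative source–receptor surrogate (rows
  sum to ≤ 1), not an atmospheric model; the coastal exposure pair is
  generated by a habitat-attenuation factor, not wave physics.
* The published global headline numbers (e.g. 90% of NCP on ~30% of
  land) are **not** reproducible from this package and are not claimed by
  any test; every number this vignette or the README cites is computed by
  the package itself on synthetic worlds.

## Reproducibility

`run_pipeline()` is deterministic for a fixed `(config, seed)`: rerunning
the 64×64 reference configuration produces byte-identical rasters, CSVs
and GeoJSON, and an identical manifest up to wall-clock timings. The
manifest records content hashes of every layer and solution so
regressions surface as hash changes.
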