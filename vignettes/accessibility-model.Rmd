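---
title: "Floating catchment area accessibility: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Floating catchment area accessibility: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcaccess)
```

## The problem and the model

Access to a capacitated, freely chosen health service — the motivating case
is NHS dentistry in England, where practices hold annual contracts in Units
of Dental Activity (UDA) and patients may attend any practice — is poorly
captured by indicators that either trap demand inside administrative
boundaries (provider-to-population ratios) or let one provider serve every
catchment it falls into (reachable-provider counts). Floating catchment
area (FCA) methods fix both by letting overlapping catchments compete for
finite capacity.

This package implements a three-step FCA with three refinements:
Huff-probability demand splitting, variable (Q-nearest) catchments, and
travel-time decay applied to absolute time differences.

Given zones $i$ with populations $Pop_i$, providers $j$ with capacities
$S_j$, and travel times $d_{ij}$ in minutes:

**Step 0 — catchments.** $B_i$ is the set of providers whose time is at
most the $Q$-th smallest reachable time from $i$ (default $Q = 10$).
Because times are stored to one decimal place, ties at the $Q$-th value are
common and are all included, so the effective $Q$ may exceed the target;
zones with fewer than $Q$ reachable providers keep all of them.

**Step 1 — demand allocation.** With travel cost
$\Delta_{ij} = d_{ij} - d_i^{\min}$ (the excess over the zone's nearest
reachable provider) and decay weight $f$,
$$P_{ij} = \frac{S_j\, f(\Delta_{ij})}{\sum_{k \in B_i} S_k\, f(\Delta_{ik})},
\qquad D_j = \sum_i P_{ij}\, Pop_i .$$
Each served zone's row of $P$ sums to one, so total allocated demand equals
the served population — demand is independent of provision.

**Step 2 — ratios.** $R_j = S_j / D_j$, capacity per allocated person.

**Step 3 — indices.**
$$SDI_i = 1000 \sum_j P_{ij} R_j, \qquad
  SPAI_i = \sum_j P_{ij}\, f(\Delta_{ij})\, R_j .$$
The Spatial Density Index measures availability in capacity units per 1000
residents; the Spatial Accessibility Index discounts each catchment
provider's ratio by its decay weight, so distant capacity counts for less.
Since $f \le 1$, $SPAI_i \le SDI_i / 1000$, with equality only when every
member sits at the zone's minimum time.

Two exact identities anchor the test suite: $\sum_j D_j$ equals the served
population, and $\sum_i Pop_i \, SDI_i = 1000 \sum_{j: D_j > 0} S_j$. The
second means the population-weighted mean SDI is just 1000 times
system-wide capacity per head — availability indices redistribute capacity,
they do not create it. It also yields a closed-form prediction for
scenarios: removing a provider that leaves all remaining demands positive
lowers the population-weighted mean SDI by exactly $1000\,S_{removed} /
\sum_i Pop_i$.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `q_target` | 10 | providers | patients searching for NHS dental care report contacting up to ten practices; with a choice set this wide the decay parameters matter less |
| `d_max` | 30 | minutes | of the order of the typical zone-to-provider car journey |
| `f_dmax` | 0.05 | — | a 30-minute journey is weighted at 5% of a zero-cost one |
| decay family | gaussian | — | $f(d) = f_{dmax}^{(d/d_{max})^2}$; an exponential family $f_{dmax}^{d/d_{max}}$ is also provided |
| `delta_mode` | absolute_difference | — | zones are compared on extra minutes beyond their nearest provider, not on ratios of travel times; `"raw"` retained for comparison runs |
| `sentinel_minutes` | 120 | minutes | marker for unreachable pairs, never a real travel time |

Both decay families are parameterised solely by the two anchors
$f(0) = 1$ and $f(d_{max}) = f_{dmax}$, exactly, for any valid
$d_{max} > 0$ and $f_{dmax} \in (0,1)$; this makes decay-profile curves
reproducible for any anchor choice. The precise functional family used in
the original FCA literature is not recoverable from the anchors alone, so
the family is an explicit, documented choice here, with gaussian as the
default; with $Q$-nearest catchments the two families give similar
orderings.

## The synthetic-region generator

The generator exists so that every downstream stage is testable without
external downloads. It emulates the statistical structure of the English
inputs:

* zone populations uniform on [1000, 3000] persons (the census
  neighbourhood range), centroids uniform on a square region;
* provider capacities log-normal with parameters solved in closed form from
  the target median $m$ = 10 740 and mean $M$ = 13 277 UDA/year
  ($\mu = \log m$, $\sigma^2 = 2\log(M/m)$). The log-normal is the simplest
  two-parameter right-skewed family matching a median below the mean; it is
  a stand-in, not an inference about the real contract distribution;
* provider locations biased toward zone-dense areas (probability 0.8 of
  jittering a random zone centroid, sd 1 km), else uniform;
* straight-line car times at 40 km/h, rounded to one decimal place, with
  pairs at or beyond 32 km crow-fly distance set to the 120-minute
  sentinel. Rounding happens in the generator, not just in file readers, so
  ties at the $Q$-th nearest time arise naturally, as they do in real
  one-decimal journey-time data;
* a deprivation quintile drawn uniformly, and an urban/rural label from a
  density proxy (a zone is urban when at least `urban_k = 10` other
  centroids lie within `urban_radius_km = 5`). Real deprivation and
  settlement classifications are external lookups; the proxy only has to
  produce plausibly contrasting strata.

What the generator does **not** emulate: road-network travel times and
their asymmetries, coastal and administrative geography (so true edge
effects appear only via the crow-fly cutoff), spatial autocorrelation of
deprivation, multi-modal travel, and any demand heterogeneity beyond
population size. Passing tests therefore demonstrate the correctness of the
computation and its invariances — not that synthetic index distributions
match any real region's.

## Numerical and convention choices

* **Ties** are resolved on the stored one-decimal travel times: every
  provider equal to the $Q$-th smallest time is a member.
* **Sentinel entries are never members**, regardless of $Q$; a zone with no
  reachable provider gets `NA` indices and an `empty_catchment` flag rather
  than zeros, so "no access" cannot be confused with "zero ratio".
* **Zero-demand providers** get $R_j = 0$ with a `zero_demand` flag rather
  than an infinite ratio, and drop out of the supply-conservation identity,
  matching its algebra. A catchment whose members all have zero capacity
  cannot be normalised and is treated as empty.
* **Quantiles** in stratified summaries use the linear-interpolation rule
  (R type 7). **Ranks** use rank 1 = highest index and average ranks for
  ties; scenario rank change is rank-after minus rank-before, so positive
  means deterioration.
* **Scenarios recompute everything.** Edits perform matrix surgery on the
  inputs (drop/add travel rows and columns; added providers get a column
  computed from coordinates with the generator's conventions), then the
  whole model — catchments included — is rerun. At desk scale correctness
  beats incremental updating.
* **Aggregation** to parent geographies uses population-weighted means over
  zones with defined indices; population weighting is what preserves the
  national mean exactly across aggregation levels. Both the total and the
  served member population are reported.

## Problem sizes used for verification

The test suite runs the full pipeline against an independent per-zone loop
reference implementation on 50-zone by 30-provider instances (agreement to
1e-10), checks catchment construction against a sort-based oracle on
50 by 50 instances, demand conservation on one hundred 20 by 8 random
instances, and generator calibration at 5000 providers and 10 000 zones.
The per-capita coverage check rescales a 400-zone, 80-provider synthetic
region to the national totals of 56 489 800 residents and 86 381 814 UDAs,
recovering 1.53 capacity units per capita through the model's conservation
identity. These sizes make every identity sharp while keeping the whole
suite fast.

## Limitations

* Straight-line travel at a single speed; no routing, congestion or
  multi-modal travel.
* A single deterministic capacity figure per provider; no treatment-band
  mix, delivery shortfalls or registered-list dynamics.
* Demand equals resident population; no discounting of people who would
  not seek the modelled service.
* Planar coordinates in km; no geodesy or boundary polygons.
* Indices inherit the edge bias of any bounded study region: zones near
  the boundary lack the providers beyond it, and the sentinel cutoff makes
  that explicit rather than fixing it.
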