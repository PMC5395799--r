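---
title: "Travel-time scenario modelling for health-service access"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Travel-time scenario modelling for health-service access}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accesskit)
```

## The model

`accesskit` estimates how long people take to reach health facilities
across a landscape where travel is multi-modal: walking off any network,
wading or being blocked by watercourses, and driving once a road is
reached. The analysis is raster-based throughout, because network-only
routing cannot represent the off-road walking that dominates journeys in
remote rural settings.

The pipeline has four stages.

1. **Land cover.** Vegetation (classes 1–4: Forest, Grass, Bare, Scrub),
   watercourses and roads are mosaicked into a single twelve-class grid.
   Watercourses are derived from elevation: depressions are filled
   (priority-flood), each cell drains to its steepest D8 neighbour, flow
   accumulation marks stream cells, and Strahler ordering sizes them.
   Orders 1–4 become classes 101–104; orders of five and above are capped
   into class 105, treated as impassable at any time of year. Roads are
   rasterised into classes 201 (national), 202 (provincial) and 203
   (local); at crossings the faster class wins, and roads overprint
   streams (the bridge assumption — a flooded crossing is modelled by
   drawing a barrier, which is the interactive workflow the toolkit
   supports, not by severing every crossing automatically).

2. **Friction surface.** A speed lookup assigns each class a travel speed
   in km/h, converted per cell to traversal seconds
   `t = cell_size / (v · 1000/3600)`; at the default 50 m cells, Forest
   (1 km/h) costs 180 s, Grass 90 s, a local road (10 km/h) 18 s. A speed
   of zero maps to the 99,999 s sentinel, a hard barrier. Scenario
   modifiers are applied in a fixed order so composition is reproducible:
   drawn land-cover edits; road-speed overrides; the walking-mode factor
   (assisted halves walking speed, stretcher cuts it to a fifth) on
   off-road classes only, road travel being vehicular by default
   (`walking_slows_roads` flips this); weather (rainy closes the three
   largest stream classes, flooding all five); night (all speeds × 0.8,
   i.e. seconds × 1.25); finally drawn barriers (1–600 minutes per cell),
   which always win.

3. **Accumulated travel time.** Two engines share one move model: the
   sixteen moves of a 5×5 neighbourhood (axial, diagonal and knight
   steps) at their exact Euclidean lengths 1, √2 and √5 cell units, a
   move costing its length times the mean of the two cells' traversal
   seconds. The *chamfer* engine initialises the accumulated grid to the
   sentinel (destinations at 0) and relaxes it with four sequential
   scans — row-major forward and backward, then column-major forward and
   backward — optionally repeating until no cell changes. The *exact*
   engine is multi-source Dijkstra on the same move graph (igraph
   backend) and doubles as the oracle for the chamfer engine. Zone maps
   reclassify minutes into the six half-open bands 0–15, 15–30, 30–60,
   60–90, 90–120, 120+ (top bound 999,999).

4. **Agent simulation.** A patient agent placed on the accumulated
   surface descends it to the destination; car agents travel road cells
   only, always toward a destination, and a patient sharing a cell with a
   car rides the rest of the way. The simulation reports distance, time
   and average speed, contrasting the raster assumption (transport
   available instantly on reaching a road) with traffic that actually has
   to show up.

## Numerical choices

* **Sentinel.** 99,999 s marks impassable cells in cost grids and
  unreachable cells in travel-time grids; accumulated values are capped
  there. Cells at the sentinel are removed from the move graph rather
  than priced, so barriers cannot leak long detours.
* **Knight moves cannot jump barriers.** A √5 move is allowed only when
  both cells flanking its midpoint are passable, in both engines and in
  agent movement. Without this rule a one-cell-thick barrier ring would
  be permeable, which contradicts the drawn-barrier workflow.
* **Chamfer metric error.** With exact step weights the chamfer metric
  overestimates straight-line distance by at most
  √(1+(√5−2)²) − 1 ≈ 2.75 %, attained near the (4,1) direction; the test
  suite measures exactly this value on a uniform grid. Four scans
  reproduce the exact engine to within about 1 % on smooth friction
  fields; on strongly road-threaded surfaces optimal paths wind, and the
  convergent mode (`converge = TRUE`) is the appropriate engine (it
  agrees with Dijkstra to machine precision).
* **Depression filling.** Priority-flood with an epsilon gradient
  (default 10⁻⁶ m per step) so D8 directions exist across filled flats;
  `eps = 0` gives the textbook fill to the exact spill elevation.
* **D8 ties** are broken in the fixed order E, SE, S, SW, W, NW, N, NE
  for cross-platform determinism.
* **Stream initiation** defaults to an accumulation of 0.5 % of the
  grid's cells — a conventional desk-study choice; the threshold is
  exposed everywhere it matters.
* **Agent descent.** The patient moves to the strictly-smaller
  16-neighbour minimising `tt[n] + move seconds`. This locally
  time-optimal rule follows a shortest-path tree on a consistent
  surface, so a walking-only journey reproduces the surface value at the
  start cell; descending by smallest neighbour *value* alone can pay
  large move costs for small surface drops and overshoot the surface by
  tens of percent on road-threaded landscapes.
* **Cars** spawn at boundary road cells by a seeded exponential
  inter-arrival process at `traffic_intensity` per minute and descend a
  road-constrained travel-time field, so they are always
  destination-bound. Pickup is co-location on a cell during overlapping
  occupancy intervals; a waiting patient keeps walking rather than
  standing still. Since cars and the walking patient both price road
  moves from the same cost grid, they move at equal speed on a straight
  road and pickup is a phase coincidence — realistic for same-direction
  traffic, and the reason pickup statistics are assessed over many
  seeded runs.
* **Service availability** is destination filtering: facilities carrying
  `needs_doctor = TRUE` drop out when the scenario's service factor is
  `doctor_away`. Modelling it instead as an added delay at the facility
  would be a one-line change in `build_cost_grid`'s barrier stage but is
  not the default.

## The synthetic landscape

Every module is testable offline via `generate_landscape()`: a DEM of
low-pass-filtered noise on a central dome (default relief 120 m — enough
for multi-order stream networks without cliffs), vegetation from a
smoothed random field cut at fixed quantiles (patchy, all four classes
present), one national trunk road crossing the extent with provincial
branches and local spurs, and facilities placed on the trunk road. The
default extent mirrors the demonstration configuration of 600 × 600
cells at 50 m (30 × 30 km); tests and the acceptance script use
100 × 100 so the full pipeline runs in seconds.

What the generator does *not* emulate: real geomorphology (valleys are
noise-scaled, not fluvially carved), land-cover/terrain correlation
beyond a mild elevation nudge, road networks that follow terrain, or
population distribution (individuals are placed explicitly, matching the
toolkit's case-by-case usage). Passing tests therefore demonstrate the
*mechanics* — drainage, ordering, mosaicking, cost accumulation, zoning,
agent transport — not calibration against any real region.

## Limitations

* Costs are isotropic; slope-dependent walking speeds are a natural
  extension of the cost-grid stage but are out of scope.
* The four-scan chamfer engine underperforms on labyrinthine cost
  surfaces; use `converge = TRUE` or the exact engine there.
* Travel-time grids share the 99,999 sentinel with cost grids, so a
  genuinely reachable cell more than ~27.8 h away saturates; at desk
  scales this does not occur.
* Car behaviour is deliberately minimal (single vehicle class, no
  round-trip ambulance routing, no real network topology).
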