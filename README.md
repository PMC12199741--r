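# driftback

Tools for asking, and answering, a concrete question in marine invasion
ecology: **when a cryptogenic organism appears on a remote reef, where
could the surface ocean have brought it from?** The package implements the
full inferential chain for the floating-debris pathway — backtracked
Lagrangian dispersal over gridded surface currents with hexagonal coastal
settlement polygons, drifter-based calibration of the horizontal
diffusivity, landing statistics with covariate tests, a pooled-qPCR
environmental-DNA screening pipeline for the candidate source regions the
model nominates, and DNA-barcode percent-identity ranking for confirming
any detection — plus a synthetic-data module that generates every input
with known ground truth, so the whole chain is testable offline.

## The model

Surface-restricted particles follow

    dx = u(x, t) dt + sqrt(2 K dt) * N(0, 1)       (per horizontal axis)

with `u` interpolated bilinearly in space and linearly in time from daily
current snapshots (RK4 advection, hourly sub-steps, daily output), run
*backward* in time from the observation site: the landing cell of a
backtracked particle is its inferred origin. Settlement cells are
1°-wide hexagons activated by coastal habitat polygons, minus exclusion
regions (for example the observation archipelago itself, to forbid
self-recruitment). The one free physical parameter, the horizontal eddy
diffusivity `K` (m²/s), is calibrated by backtracking ensembles from the
final fixes of satellite-tracked debris and scoring candidate values by
minimum passing distance to the known origin (haversine, R = 6371 km),
compared with exact-enumeration rank-sum tests under Bonferroni
correction.

Downstream decision rules: any technical replicate with positive starting
quantity (Cq called and `10^((Cq - intercept)/slope) > 0`) is an eDNA
detection; pooled screens carry a spiked positive pool so a
failed-to-amplify spike invalidates the pool instead of passing silently;
a candidate population is confirmed only when rbcL, COI and SSU all
exceed 99% identity *and* an eDNA detection corroborates.

## Worked example

Backtrack ten days of daily releases over a synthetic source island whose
outward surface flow funnels backtracked particles home:

```r
library(driftback)

island <- list(center = c(200, 25), radius = 0.4)
field <- make_field(field_spec("convergent_sink", center = island$center,
                               rate = 2e-6, outward = TRUE,
                               islands = list(island),
                               bbox = c(185, 215, 12, 38), res = 0.5,
                               start = "2020-01-01", end = "2020-02-15"))
grid <- build_hex_grid(c(185, 215, 12, 38), cell_size = 1)
settlement <- activate_cells(grid, make_coastline(list(island)))

schedule <- release_schedule(site = c(205, 29), particles_per_day = 100,
                             start_date = "2020-02-01",
                             end_date = "2020-02-10")
run <- run_simulation(field, schedule, settlement,
                      transport_config(K = 10, direction = "backward",
                                       seed = 1))
print(run)
#> <dispersal_run> 1000 released (backward)
#>   active          0
#>   landed          1000
#>   escaped_domain  0
#>   expired         0

tab <- tally_landings(run$landings, n_released(schedule))
format_percent(tab$count, n_released(schedule))
#> [1] 100
```

Every backtracked particle lands in the island's settlement cells: the
landing table concentrates 100% of released particles on the true source,
which is exactly what the fixture was built to make decidable. The
calibration counterpart, `calibration_study(seed = 1, n = 1000)`, selects
`K = 10` m²/s from the {0.5, 5, 10, 20, 50} sweep with mean passing
distances of 16.09, 15.28, 15.14, 15.52 and 16.69 km, reports
{5, 10, 20} as statistically indistinguishable, and rejects the
0.5 m²/s arm at Bonferroni-adjusted p = 6.9e-12.

The full analysis sequence lives under `analysis/` as numbered scripts,
run from the repository root in order:

```sh
Rscript analysis/01_synthesize_inputs.R        # synthetic world -> results/inputs/
Rscript analysis/02_backtrack_source_recovery.R
Rscript analysis/03_calibrate_diffusivity.R
Rscript analysis/04_edna_screen.R
Rscript analysis/05_barcode_rank.R
```

Each reads the previous steps' outputs under `results/`, prints what it
found, and writes its tables there (01 regenerates the NetCDF forcing, so
run it first in a fresh clone).

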