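---
title: "Tracing a marine introduction: models and decision rules in driftback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing a marine introduction: models and decision rules in driftback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftback)
```

## The problem

A nuisance red alga appears on a remote Pacific atoll with no known
conspecific population anywhere else. If it arrived attached to floating
marine debris, the surface circulation constrains where it could have come
from. driftback implements the full inferential chain for that situation:

1. **Backtracked Lagrangian dispersal** — particles released daily at the
   observation site are integrated backward in time over gridded surface
   currents until they first contact a coastal settlement cell; the landing
   pattern ranks candidate source regions.
2. **Diffusivity calibration** — the one free physical parameter, the
   horizontal eddy diffusivity `K`, is chosen by backtracking ensembles
   from the final fixes of satellite-tracked debris and scoring candidate
   values by minimum passing distance to the known origin.
3. **Landing statistics** — per-cell tallies, bounding-box region shares,
   drift-time contrasts, density clouds, and rank-sum tests of landing
   rates against ENSO phase and season.
4. **eDNA screening** — a pooled qPCR decision pipeline (with spiked
   positive pools guarding against dilution-induced false negatives) that
   classifies each candidate region as detected, presumed negative,
   invalid, or contaminated.
5. **Barcode confirmation** — percent-identity ranking of candidate
   sequences against the reference organism, and a conservative
   multi-marker rule for declaring a population confirmed.

Every stage runs offline: a synthetic-data module generates velocity
fields, coastlines, drifter tracks, ENSO series, amplification curves and
sequence families with known ground truth.

## Transport model

Particles are restricted to the surface and obey advection plus an
uncorrelated random walk:

- **Advection** uses classical fourth-order Runge-Kutta over a velocity
  field interpolated bilinearly in space (wrap-aware across the 0/360
  longitude seam; the package convention is degrees east in [0, 360)
  because the domain of interest spans the antimeridian) and linearly in
  time between daily snapshots. Backward integration negates velocities
  and runs the clock down; for `K = 0` it is the exact time-reverse of the
  forward map, which the tests verify to sub-kilometre closure over 30
  days.
- **Diffusion** adds independent Gaussian displacements per horizontal
  axis with variance `2*K*dt` (m²) per sub-step, converted to degrees at
  the particle's latitude (111,195 m per degree, times cos(latitude) for
  longitude). The default `K` of 10 m²/s is the drifter-calibrated value;
  the calibration sweep covers 0.5-50 m²/s.
- **Sub-stepping**: one hour internally, daily output. Daily output is the
  resolution at which positions are logged, settlement is tested and
  landings are dated. Settlement at finer resolution is deliberately not
  tested: the daily convention defines what a "landing day" means here.
- **Coasts**: masked grid nodes contribute zero velocity to interpolation
  (no NaN propagation near shorelines). A sub-step that would strand a
  particle on a land node resamples its diffusion kick up to 10 times,
  then leaves the particle in place for that sub-step. This suppresses
  spurious beaching without biasing open-water statistics.
- **Random numbers**: one master seed; each particle's kicks come from a
  substream keyed by particle id (and day), so results are independent of
  batching and execution order. Backtracking applies a fresh random walk
  rather than attempting to "undo" forward diffusion, the standard
  practice for adjoint-free Lagrangian backtracking.
- **Bookkeeping**: a particle is exactly one of active, landed,
  escaped_domain, or expired at every output step, and the four classes
  always sum to the number released. Landing assigns the first active cell
  containing the daily position; drift time is the whole-day difference
  between landing and release.

## Settlement geometry

Settlement cells are pointy-top hexagons of 1 degree edge-to-edge width
laid out in planar lon/lat, the shape and scale used for settlement
polygons in individual-based dispersal modelling (hexagons hug coastlines
better than squares). A cell is activated when it intersects a habitat
polygon and deactivated when it intersects any exclusion polygon — whole
cells, because excluding a region means removing its polygons outright
(self-recruitment back to the observation region is excluded the same
way). Point location uses axial-coordinate rounding with an explicit
containment check; points on shared edges resolve to the lowest cell id,
making location a total, deterministic function. Hexagon size in degrees
(rather than equal-area cells) matches the figure scale of the original
analysis; the tessellation itself is checked against brute-force
containment oracles.

## Diffusivity calibration

Each candidate `K` backtracks `n = 1000` particles from a drifter's final
fix; each particle is scored by the minimum great-circle distance
(haversine, sphere radius 6,371 km) between its daily positions and the
origin. Candidates are compared by mean passing distance with pairwise
rank-sum tests (Bonferroni-corrected), selecting the smallest mean and
reporting the statistically indistinguishable set alongside — sweeps of
this kind typically leave a broad indistinguishable plateau with only the
smallest candidate clearly worse, so honest reporting of the
indistinguishable set matters as much as the argmin.

The synthetic calibration study (`calibration_study()`) emulates the two
features that make the sweep identifiable in the real world. Three tagged
debris objects escape a monitored atoll inside a rotating gyre (30-day
period) and drift with the true `K = 10` m²/s for different lengths of
time — two for three gyre revolutions, one for one and a half —
as with real tag deployments, where tags escape months apart and log
very different drift durations. The two regimes carry
complementary information: on a long recirculating drift, a backtracked
ensemble passes the origin repeatedly, and an under-diffused ensemble
(0.5 m²/s) retraces one wrong path on every pass, so its passing
distances stay pinned at the deterministic error while better-matched
ensembles explore past it; on the shorter single-pass drift the ensemble
gets one close approach, which an over-diffused ensemble (50 m²/s)
scatters. Ensembles are pooled per candidate across tags, as one pools real
loggers, and the pooled score profile has its minimum at the
true diffusivity with a sharp rise at 0.5 — in the shipped configuration
(seed 1, n = 1000 per candidate per tag) the selection is exactly
10 m²/s, the indistinguishable set is {5, 10, 20}, and 0.5 versus the
selection has Bonferroni-adjusted p below 1e-10. The rank-sum machinery
itself is validated against exhaustive enumeration. Geometries dominated
by a single regime are genuinely unidentifiable with this score — purely
recirculating flow rewards ever-larger spread, purely transient flow
ever-smaller — which is worth knowing before applying the method to a
new drifter dataset.

Two properties worth noting when interpreting calibration output on real
data: the minimum-passing-distance score is a *threshold* diagnostic (it
cleanly rejects diffusivities too small to explore the error of the
deterministic path, but separates moderate and large values only weakly),
and the score is bounded below by deterministic model error, which no
choice of `K` can remove.

## Statistics

Rank-sum (Mann-Whitney/Wilcoxon) tests are computed by exhaustive
enumeration of all group assignments of the pooled mid-ranks whenever both
groups have at most 8 observations — ties included, which is why the
package carries its own implementation — and by the tie-corrected normal
approximation otherwise. Bonferroni correction multiplies each raw p by
the family's comparison count, capping at 1. ENSO/season association bins
landings by landing month, labels months by phase and climatological
season (DJF/MAM/JJA/SON), and tests monthly counts pairwise between labels
within each region; the tests are unpaired by default because phases
occupy disjoint, unequal sets of months (a paired variant is available for
designs with a genuine pairing unit). Report percentages are rounded
half-up to one decimal — 44,336 of 584,300 prints as 7.6 — and the exact
values are kept alongside.

## eDNA decision rules

Cq is the linearly-interpolated first crossing of the fluorescence
threshold; quantification inverts the least-squares standard-curve line
(Cq on log10 copies), so `quantify()` is exact at fitted points and an
uncalled Cq maps to zero copies. Amplification efficiency is
`10^(-1/slope) - 1`; slope -3.3219 is perfect doubling. The plate
threshold is an input (real instruments auto-compute it); a fallback of
baseline mean plus 10 SD over cycles 3-15 is provided for plates without
one. The region decision table is deliberately strict: any control (NTC or
equipment blank) amplification marks the region contaminated; a spiked
positive pool that fails to amplify invalidates the screen (the spike
exists precisely to detect dilution-induced false negatives in pools,
which are capped at 20 members); any positive replicate in the sample pool
is a detection that triggers a re-screen recommendation; otherwise the
region is presumed negative — "presumed" because eDNA absence is not
observation of absence. Replicate reliability uses a centred moving
average (default window 3 cycles) of the replicate-mean trace compared to
the threshold: a deliberately dependency-free smoother whose behaviour on
concordant, flat, and single-spike replicates is pinned by tests.

## Barcode identity

Pairwise global alignment is Needleman-Wunsch with match +1 / mismatch -1
/ linear gap -2 and deterministic tie-breaking (diagonal, then up),
verified against a brute-force enumeration oracle. Percent identity
excludes columns with a gap in either row and strips terminal-gap columns
first: herbarium amplicons vary in length, so ragged ends carry no signal,
while internal indels still shrink the denominator. Ranking against the
reference sorts descending with ties broken by candidate id, making the
report stable under input permutation. The confirmation rule is the
conservative conjunction: all three corroborating markers (rbcL, COI, SSU)
above 99% identity *and* an eDNA detection confirm; barcodes alone are
provisional; anything less is rejected.

## Synthetic data: what it does and does not emulate

All analytic fields prescribe closed-form motion in degree space and
convert to physical m/s with the integrator's own metric, so test oracles
(straight lines, circles, exponential spirals) are exact and bilinear
re-interpolation of the gridded field is essentially lossless for the
linear-rate fields. The four field kinds: `uniform` (analytic
displacement), `solid_body` (radius conservation, rotating calibration
gyre), `double_gyre` (steady: divergence-free round-trip tests; with
`epsilon > 0` the classic time-periodic separatrix oscillation whose
advection is chaotic), and `convergent_sink` (with `outward = TRUE`, a
source island whose backtracked flow funnels every particle home — the
decidable end-to-end fixture). Drifter tracks are forward simulations
observed at 4-hour cadence with optional position noise; qPCR curves are
logistic sigmoids whose threshold crossing solves exactly to the
standard-curve Cq of the requested copy number; marker families mutate a
reference at per-site probability `d`, giving expected identity
`100(1 - d)`%.

What passing tests on these fixtures show: the integrator, grid, decision
rules and statistics are correct, and the whole chain recovers a known
source and a known diffusivity under conditions where recovery is
decidable. What they do not show: skill against mesoscale ocean dynamics
(eddies, boundary currents, ENSO-dependent circulation), amplification
inhibitors or hands-on plate pathologies, or alignment ambiguity in highly
divergent sequence sets. Conclusions about real oceans still require real
forcing fields.

## Problem sizes and numerical choices

The shipped analyses and tests use deliberately modest scales chosen as
the smallest that make each property decidable: source-recovery runs
release 100 particles/day for 10 days (1,000 backtracked particles);
calibration uses 1,000 particles per candidate per tag across three
pooled tags; the diffusion variance check uses 10,000 particles. Tolerances
follow the oracle error structure: analytic trajectory checks at 0.1% or
tighter, stochastic ensemble checks at 3 sigma or the stated 5%,
quantification round-trips at 10% (the sigmoid shape, not the line,
limits them). Degenerate inputs are contracts, not surprises: empty
settlement sets land nothing; `K = 0` collapses ensembles to one
deterministic trajectory; empty habitat activates nothing; zero-copy
curves never cross threshold; all are tested.

## Known limitations

No windage, Stokes drift, or object-density classes in transport; no
geodesic polygon geometry (planar lon/lat is the convention at 1-degree
scale); no multiple-sequence alignment (pre-aligned input is consumed
as-is); ENSO labels are an input series, not derived from SST; the
GAM-style visual reliability criterion of instrument software is replaced
by a documented moving-average rule.
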