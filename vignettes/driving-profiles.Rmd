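---
title: "Building naturalistic driving profiles from breadcrumb GPS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building naturalistic driving profiles from breadcrumb GPS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivecrumb)
```

## The data-generating process

An OBDII-plugged GPS logger samples the vehicle every 30 seconds from
ignition-on to ignition-off, emits a location ping every 3 hours while
parked, and tags special rows for ignition events, adverse-driving alerts and
device health. The vendor delivers two daily CSV feeds: a *breadcrumb* file
(one row per fix: vehicle code, UTC timestamp, latitude/longitude, speed,
odometer, event type, and per-event speed extras) and an *activity* file (one
row per trip: start time, endpoints, duration, distance — rounded to 0.1 km
and reported in miles — and alert counts). A *trip* is the ordered breadcrumb
sequence between an ignition-on and the next ignition-off of one vehicle.

These devices fail in characteristic ways, and the cleaning stage encodes
each failure as an audited rule:

* **Coordinates.** Connect/disconnect glitches report (0, 0); satellite-lock
  failures can report a fix on another continent. Rows outside a configurable
  continental-US envelope (lat 24.5–49.5, lon −125 to −66.9 — a standard
  CONUS rectangle, since no tighter bound is canonical), exactly zero on
  either coordinate, or non-finite are removed. Because one bad fix makes the
  whole trip's geometry untrustworthy, all breadcrumbs sharing the trip go
  with it. The zero test is exact equality — the device-fault signature — not
  an epsilon ball, so legitimate fixes near the equator/prime meridian (none
  exist in CONUS) are not a concern.
* **Duplicates.** No two rows of one vehicle may share a timestamp. The first
  occurrence in file order is kept. Observed duplicates are byte-identical
  retransmissions; if a duplicate ever disagrees in position it is kept out
  all the same but flagged `conflict` for review, since that indicates a
  different failure than retransmission.
* **Trip records.** Rows with `NA` end coordinates (signal loss, or the
  vendor's "abandoned" second-trip-start quirk) or a zero start coordinate
  are removed with per-reason logging.
* **Defective devices.** A device can stream zeros for weeks. A vehicle is
  flagged when any rolling 7-day window has more than 50% zero-coordinate
  crumbs with at least 25 crumbs in the window; the floor keeps a single
  stray zero from flagging a healthy vehicle. The window/fraction are
  package choices (the failure mode is "multiple weeks" scale) and are
  configurable.

Cleaning order is coordinates → duplicates → trip records. The first two
commute on byte-identical duplicates (the test-suite checks the kept set is
order-invariant); trip-record filtering is independent of both.

Trip reconstruction closes an open trip at the next ignition event: a second
ignition-on within 60 s with at most one intervening crumb marks the first
start "abandoned" (matching the observed several-seconds quirk); any other
ignition-on while a trip is open flags the open trip unterminated; an
ignition-off with no open trip is quarantined. Idle pings never join a trip.

## Local time and light phase

All device timestamps are UTC. Zone resolution uses a fast-path rectangle in
the interior of the Central zone (most cohort data is Midwestern; the box is
strictly interior, so the shortcut can never disagree with the polygon
result) and falls back to point-in-polygon lookup. The packaged polygons in
`tz_us_simplified.geojson` are deliberately simplified meridian slabs — fine
for synthetic worlds and tests, wrong near real zone borders; production use
should supply real boundary polygons as GeoJSON. UTC→local conversion is the
tz database via `lubridate::with_tz()`, so DST is exact and round-trips are
the identity.

Solar events come from the NOAA low-accuracy solar-position equations,
iterated so the ephemeris is evaluated at the event time: sunrise/sunset at
solar elevation −0.833° (refraction plus half the disc), civil twilight at
−6°. Accuracy is about ±1 minute for |lat| < 60; the tests pin twelve
site/date combinations to independently computed NOAA reference values
within 2 minutes, and polar day/night return explicit absent markers.

A trip's light phase is decided by its **departure** instant and place:
dawn = [civil dawn, sunrise), day = [sunrise, sunset),
dusk = [sunset, civil dusk), night otherwise. Counting by departure matches
how month-over-month "trips at night" tables are built; trips crossing
sunset are deliberately not split. Reports that prefer a wide night
definition get `n_trips_not_day` (dawn + dusk + night) alongside the strict
counts; the strict definition is the default because civil twilight is the
conventional boundary for "dark" driving.

## Spatial profile

All geometry runs in a centred equirectangular projection (metres east/north
of the driver's median fix) with an exact closed-form inverse; scale error is
below 0.5% within ~100 km of the centre at mid-latitudes, which is ample for
metro-scale driving areas. Distances against a haversine oracle and 0.1-m
round-trips are part of the test-suite.

* **Primary locations.** Ignition-on fixes approximate parking events.
  Clusters are connected components of the graph joining fixes within 20 ft
  (single linkage at a fixed distance — the aggregation-distance idiom);
  components with fewer than 3 points are noise and discarded. A cluster
  whose membership reaches 10% of the driver's ignition-on fixes over the
  whole window is a primary location (home and, for some drivers, a second
  home or workplace). Membership count, not a point-in-polygon recount,
  defines the share: equivalent for convex hulls of the members and robust
  when the hull is degenerate.
* **Driving area.** Convex hull of a driver-month's breadcrumbs, area in
  km². Fewer than three distinct non-collinear points is degenerate: zero
  area, excluded from overlaps.
* **Mean center.** The unweighted mean of fixes — always inside the hull.
* **Overlap.** Consecutive-month hull intersections, the area common to all
  months, and the ratio common/total. "Total" is the area of the union of
  the monthly hulls (the sum of monthly areas double-counts shared territory
  and can push the ratio arbitrarily low; `total = "sum"` is available for
  comparability). Convex-polygon intersection is Sutherland–Hodgman
  clipping; the union area is inclusion–exclusion over the (at most five)
  monthly hulls, exact because intersections of convex sets stay convex.
* **Unique destinations.** Buffer-dissolve counts at 100/250/500 ft: discs
  of radius r around ignition-on fixes, merged when they overlap. Two discs
  overlap exactly when their centres are closer than 2r, so the dissolved
  count equals the component count of the centre graph; tangent discs
  (distance exactly 2r) share one point but no area and are counted
  separately (strict inequality). The tests verify the graph count against
  an explicit rasterised geometric union on fixtures whose pairwise
  distances stay clear of tangency. Counts are monotone nonincreasing in
  radius; the 100-ft radius gives the most granular counts.

Periods are local-calendar months (ISO weeks available via configuration);
boundaries fall at local midnight.

## Road matching and behavior

Each breadcrumb is annotated with its nearest street-centerline segment
(`near_fid`) and distance (`near_dist`) via a grid index with ring-expansion
search, which is exact: the search stops only when the best distance found
beats the guaranteed minimum of every unexamined cell, and ties break to the
lowest segment id. Fixes farther than 100 m (configurable) from any segment
are flagged off-network rather than inheriting nonsense attributes — parking
garages and GPS glitches produce such fixes. The segment's average speed
serves as the posted-limit proxy.

Alert definitions follow the insurance-industry thresholds the devices use:
overspeeding is ≥ 6 mph above the limit proxy; hard braking a decrease and
sudden acceleration an increase of 8 and 10 mph in one second respectively.
The "8 to 10 … respectively" pairing maps the range across the
decrease/increase pair; both thresholds are config keys, so the alternative
single-band reading is one override away. Device-reported events feed the
headline profile (the device is the measurement instrument); recomputation
from crumbs is a validation channel: overspeeding as maximal runs of
consecutive crumbs at or above limit + margin (a single qualifying crumb
counts — no minimum duration is defined), and braking/acceleration only on
1 Hz traces, because 30-second breadcrumbs cannot certify one-second deltas.

Per-driver window totals use the deposited-table column convention
(`numtripsover5mo`, `avg_trip_miles5mo`, …) and cohort summaries use the
sample SD (n − 1), making cross-table reconciliation deterministic.

## The synthetic world

The simulator is the package's ground truth. Its defaults encode the
emulated study conditions: five months from 2016-07-01, one driver,
Poisson(3.7) trips/day (≈ 550 trips over the window), 30-s crumbs, 3-h idle
pings, a day-dominant phase mix with more dusk than dawn departures, and a
15 × 15 planar road grid at 500 m spacing with 25/35/55 mph speed classes
mapped to CFCC-like codes — the simplest world that exercises road matching
and the overspeeding rule. GPS noise is isotropic Gaussian, sd 5 ft parked
and 15 ft moving: consumer-GPS magnitude, chosen so 20-ft clustering stays
meaningful rather than trivially tight.

The schedule is a marked point process: each trip's origin is drawn from the
configured anchor shares (the rest start at ordinary destinations), its
destination uniformly elsewhere, its departure uniformly inside the
scheduled phase's solar window with interior margins so the classification
is unambiguous at the origin site. Vehicle continuity between trips is not
enforced — no pipeline stage consumes it, and the simplification buys exact,
configurable ignition-on shares. Overlapping trips are dropped at
generation. Baseline crumb speeds ride the segment speed with truncated
noise that never crosses the overspeeding threshold; injected excursions
elevate two consecutive crumbs to limit + 10 so the device event and the
recomputation channel agree by construction (verified on a uniform-limit
grid, since on mixed grids a fast-road fix near a slow cross-street can
legitimately match the slower segment). Corruption is injected by count with
a manifest log, so cleaning can be checked for *exact* removal — the
injected rows and nothing else.

What the simulator does **not** emulate: real road topology, traffic and
congestion, weather, multi-day excursions, urban-canyon multipath (noise is
i.i.d. Gaussian, not autocorrelated), or drivers sharing a vehicle. Passing
the round-trip tests therefore shows the pipeline recovers a faithful
record of this generative model exactly; it does not certify behavior under
error modes the generator lacks.

## Numerical choices and edge cases

* Clustering merges at distance ≤ link (aggregation semantics); disc
  dissolve merges strictly below 2r (tangency separates). Both ties are
  tested.
* Degenerate cluster hulls (collinear members) get a nominal 1-m buffer so
  every cluster carries a polygon.
* Nearest-segment ties within 1e-9 m go to the lowest segment id.
* DST: conversions use the tz database directly; the round-trip identity is
  property-tested. Trips whose start zone cannot be resolved (offshore
  fixes) carry `NA` phase and are excluded from phase counts, never
  silently reassigned.
* All scenario randomness flows from one `set.seed` per scenario; the RNG
  state is restored afterwards, and emitted files are byte-identical under
  regeneration.

Problem sizes in the test-suite (25 one-month validation scenarios, one
five-month end-to-end scenario, 500-point hull and 1000 × 200
nearest-segment oracle comparisons) were chosen to exercise every code path
at comfortable margins while keeping the whole suite in the low minutes on
one CPU.

## Known limitations

The cohort-statistics acceptance check needs the study's deposited
per-participant table, which cannot be redistributed here; the check runs
when a copy is supplied. The equirectangular projection is not suitable for
drivers ranging over many hundreds of kilometres — swap the projection
centre per driver (the default) rather than pooling a continental cohort in
one frame. Weekly driving areas are computed on request but monthly periods
drive the reported metrics. Under-speeding detection is deliberately out of
scope: with 30-second sampling and an average-speed limit proxy it cannot be
separated from traffic and signal effects.
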