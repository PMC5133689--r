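# drivecrumb

Naturalistic driving profiles from in-vehicle GPS breadcrumbs.

Commodity OBDII GPS loggers report a vehicle fix every 30 seconds while the
ignition is on (a *breadcrumb*), a location ping every 3 hours while parked,
and a daily trip log. Longitudinal studies of older drivers — in particular
cohorts at risk of cognitive decline — use these streams to watch how
everyday driving changes month over month: where people go, how far they
range, whether they avoid the dark, and how often the device flags aggressive
maneuvers. `drivecrumb` turns the raw daily CSV feeds into per-driver,
per-month **driving profiles** with three components:

- **Spatial** — *primary locations* (clusters holding ≥ 10% of a driver's
  ignition-on fixes, found by single-linkage aggregation at a 20-ft link
  distance with a 3-point minimum); the *driving area* (convex hull of a
  month's breadcrumbs, km²) with month-over-month overlap metrics
  (ratio = area common to all months / union area); the unweighted *mean
  center*; and *unique destinations* — connected components of the union of
  discs of radius 100/250/500 ft around ignition-on fixes (buffer-dissolve:
  two discs of radius r merge exactly when their centres are closer than 2r).
- **Temporal** — trips classified by their departure instant against NOAA
  solar events at the departure point: dawn = [civil dawn, sunrise),
  day = [sunrise, sunset), dusk = [sunset, civil dusk), night otherwise.
- **Behavioral** — device-reported alert counts (overspeeding ≥ 6 mph above
  the posted-limit proxy; hard braking ≥ 8 mph and sudden acceleration
  ≥ 10 mph change in one second), plus an independent recomputation channel
  from the breadcrumb speeds and the nearest street segment's average speed.

The package also ships a ground-truthed **synthetic driver simulator** (road
grid, anchors, trip schedules, GPS noise, injected alerts, and the corruption
modes real devices produce: zero/NA coordinates, duplicate rows, abandoned
trip starts, defective-device runs), so every pipeline stage is testable
without any participant data.

## Worked example

Simulate two months of driving for one vehicle, write the daily vendor-style
files, and run the full pipeline back over them:

```r
library(drivecrumb)

scn   <- generate_scenario(scenario_config(months = 2, trips_per_day = 3), seed = 7)
paths <- write_scenario(scn, tempfile("drive"))
res   <- run_pipeline(paths$breadcrumbs, paths$activity,
                      segments = scn$segments, proj_center = c(38.63, -90.20))

res$cleaning_report
#> <cleaning report>
#>   breadcrumbs: 2492 in, 0 removed (coordinates 0, duplicates 0; 0 conflicting)
#>   trip records: 172 in, 0 removed

dplyr::select(tibble::as_tibble(res$profiles), local_month, n_trips,
              n_trips_day, n_trips_dusk, n_trips_night,
              n_hard_braking, driving_area_km2, n_destinations_100ft)
#> # A tibble: 2 × 8
#>   local_month n_trips n_trips_day n_trips_dusk n_trips_night n_hard_braking ...
#> 1 2016-07          83          67           11             2              9
#> 2 2016-08          89          77            6             4             15

glance(res$profiles)
#> # A tibble: 1 × 6
#>   n_drivers n_months n_trips n_trips_night n_alerts mean_driving_area_km2
#> 1         1        2     172             6       52                  28.5
```

The profile rows say: 83 trips in July (67 by day, 11 at dusk, 2 at night),
89 in August, 52 adverse-driving alerts over the window, and a mean monthly
driving area of 28.5 km². Primary locations sit in
`attr(res$profiles, "primary_locations")` — here the detector finds the home
anchor (53.5% of ignition-ons) and, as in real cohorts, a frequently visited
secondary site that crossed the 10% share. Per-driver study-window totals in
the deposited-table column convention come from
`trip_statistics(res$trips, res$activity)`, and `cohort_summary()` reduces a
cohort of such rows to mean/SD per metric. `autoplot(res$profiles)` draws the
phase/month bars; `plot_spatial_profile()` the hulls, mean centers and
primaries.

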