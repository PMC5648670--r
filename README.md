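# arscape

Residence-time analysis of animal movement paths: detecting the spatial
scales of area-restricted search (ARS) and mapping the distinct places an
animal revisits and searches intensively.

Movement ecologists routinely need to know *at what scale* an animal
responds to its resources and *where* it concentrates its time. `arscape`
answers both from a plain relocation trajectory — ordered `(t, x, y)`
fixes in planar coordinates — using residence times. Around each fix a
virtual circle of radius *r* is drawn; the residence time is

    RT(i, r) = FPT_backward(i, r) + FPT_forward(i, r),

the total time inside the circle from first entry to first exit, where
FPT is the first-passage time to the circle's perimeter scanning
backward or forward along the path. The **variance-scale curve** — the
variance of log RT (or the coefficient of variation of RT) across all
fixes, against *r* — peaks at the characteristic radius of ARS; several
distinct peaks reveal a nested, multiscale response. At a detected
scale, a four-step algorithm (filter fixes by their revisit statistics,
connect survivors within *r*, take connected components, choose a
representative fix) yields spatially distinct **revisited ARS places**,
each summarised by its mean visit duration and number of revisits.

The package also contains the validation world the framework was tested
on: a biased correlated random walk forager (heading variance
`v = v_b (1 - p cos(theta - omega))` under attraction to a target
bearing) with three strategies — simple search, simple ARS, and
hierarchical ARS with out-and-back forays — on scattered, patchy, or
two-level hierarchical resource maps, with full ground-truth logging.

## Worked example

Simulate a forager performing ARS on a patchy resource map, thin the
path to GPS-like sampling, find the ARS scale, and map the revisited
places:

```r
library(arscape)
set.seed(42)

map     <- generate_resource_map("patchy")
sim     <- simulate_forager(map, forager_config("simple_ars"))
sim
#> Forager simulation: simple_ars, 60000 steps
#>   231 consumption events, 25 ARS episodes
#>   steps by mode: explore=44963, ars=15037, foray_out=0, foray_back=0

traj  <- resample_trajectory(sim$trajectory, 10)   # 6,000 fixes
curve <- variance_scale_curve(traj)
peaks <- detect_peaks(curve)
peaks
#> 1 ARS-scale peak(s)
#>     r_peak    height prominence
#> 1 35.61015 0.9084144  0.2911983
```

The curve peaks at *r* ≈ 36 cells — just above the planted patch
footprint (items scattered 10 ± 3 cells around each centre), as expected
for this estimator, which reads slightly high. Now identify the places:

```r
r      <- characteristic_radius(peaks)
places <- identify_ars_places(traj, r, drop_single_visit = TRUE)
summary(places)
#> 17 ARS place(s) at radius 35.6102
#>   revisits: median 3 (range 2-8)
#>   mean visit duration: median 210.4 (range 130.8-443.4)

head(places$places[, c("place", "x", "y", "n_revisits",
                       "mean_visit_duration", "extent_radius")], 4)
#>   place        x         y n_revisits mean_visit_duration extent_radius
#> 1     1 446.6098 257.85921          8            414.4088      31.49490
#> 2     2 645.0336  16.79507          5            339.3227      33.33931
#> 3     3 143.4799 350.28483          8            367.1242      26.66696
#> 4     4 298.3168 386.07395          7            210.3588      42.66657
```

Each row is a spatially distinct place the forager returned to and
searched: place 1 received 8 visits averaging 414 time steps each.
One place in this run carries the `oversized` flag (component extent
above twice the analysis radius), the diagnostic for two adjacent
patches merged into one detection — flagged for inspection, never split
automatically. The gaps between consecutive visits,

```r
round(between_visit_intervals(places, place = 1))
#> [1]   132 19204     6 20297  1145  1966  7413
```

show this patch was revisited on two very different time scales: quick
returns within a foraging bout and returns after ~20,000 steps, the
order of the map's item-regeneration delay.

`run_two_step()` chains the whole analysis (both curve modes, peak
detection, radius selection, place identification) and, given an output
directory, writes curve CSVs, a peaks JSON, place tables and the exact
run configuration for reproduction. `read_trajectory()` ingests
CSV/TSV relocation files (Movebank-style column names are
auto-detected) for analysing real data.

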