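---
title: "A residence-time framework for inferring detailed space use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A residence-time framework for inferring detailed space use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Around every fix of a recorded movement path, draw a virtual circle of
radius $r$. The first-passage time (FPT) is the time the animal takes to
reach the circle's perimeter for the first time, scanning forward or
backward along the path; the residence time is

$$\mathrm{RT}(i, r) = \mathrm{FPT}_{\mathrm{backward}}(i, r) +
  \mathrm{FPT}_{\mathrm{forward}}(i, r),$$

the total time spent inside the circle from first entry to first exit.
Fixes where the animal performed area-restricted search (ARS) — slow or
tortuous movement within a confined area — carry much larger residence
times than fixes crossed en route. When $r$ matches the spatial scale of
the ARS, the contrast between ARS and non-ARS circles is maximal, so the
variance of $\log \mathrm{RT}$ (or the coefficient of variation of RT)
plotted against $r$ — the variance-scale curve — peaks at the
characteristic ARS radius. Several distinct peaks indicate a nested,
multiscale response, e.g. food patches organised in clumps.

`arscape` implements this as a two-step analysis:

1. **Scales** — `variance_scale_curve()` plus `detect_peaks()` find the
   distinct scale domains; `characteristic_radius()` turns them into
   analysis radii (upper-limit rule, see below).
2. **Places** — at a chosen radius, `identify_ars_places()` finds
   spatially distinct, revisited ARS places and summarises each by the
   revisit history of one representative location: its mean visit
   duration and number of revisits, the two scale-dependent measures the
   framework extracts.

`run_two_step()` chains both steps and writes a reproducible report
bundle.

### Revisit histories

`revisit_history()` traces every maximal sub-interval of the path spent
inside a circle, with entry and exit times located by linear
interpolation between fixes. Consecutive segments separated by less time
outside than `max_time_outside` can be merged into one visit; the merged
duration counts inside time only. There is no defensible universal
default above zero — the threshold encodes a priori knowledge of the
relevant temporal scales — so merging is off (`0`) unless requested.
All durations come from timestamps, never fix counts, so irregular
sampling is handled throughout.

### The four-step place algorithm

1. compute the revisit history of every fix at radius $r$;
2. filter: the criterion (mean visit duration, or total time inside) is
   computed per fix, and only fixes strictly above the larger of the
   criterion's mean and median survive — locations merely crossed en
   route fall below;
3. connect surviving fixes closer than $r$ (strict inequality) and take
   connected components as candidate places;
4. represent each place by its highest-criterion member (ties to the
   earliest fix); the representative's own history supplies the place
   statistics, since pooling members' histories would be partly
   pseudoreplication.

Diagnostics follow the method's known error modes: `single_visit` marks
places entered only once (long stationary stops masquerading as ARS;
`drop_single_visit` removes them), and `oversized` marks components whose
extent exceeds $2r$, the signature of adjacent places erroneously merged.
Oversized components are flagged, never split automatically — splitting
is a judgement call for the analyst. `between_visit_intervals()` exposes
the gaps between consecutive visits, whose distribution is informative
about memory-driven, trap-lining-like revisitation.

## Numerical conventions

* **Inside-ness is strict**: a point at distance exactly $r$ is outside.
  One fixed convention makes crossing, edge and component tests exact.
* **Crossings are interpolated** linearly in space and time, removing
  grid artifacts at small radii; a discrete fix-counting mode
  (`method = "discrete"`) reproduces grid-stepped analyses and agrees
  with interpolation to within two inter-fix intervals.
* **Censored residence times** (the path begins or ends inside the
  circle) are **included** by default. At radii approaching the path
  extent, censored RTs converge on the total path duration, which yields
  the canonical large-radius decline of the curve — larger circles
  contain ever more heterogeneous path segments, so RTs grow more
  similar. Excluding them (`include_censored = FALSE`) keeps only
  mid-path fixes at large radii and makes the curve rise artificially
  toward the right edge, creating spurious large-radius peaks; the
  option remains for sensitivity analyses.
* **Radius grid**: 30 log-spaced radii from twice the median step length
  to half the bounding-box diagonal. The lower bound keeps circles above
  the sampling resolution; the upper bound deliberately overshoots the
  largest scale of interest because a peak is only resolvable if the
  curve descends again beyond it.
* **Peaks**: after a 3-point moving average, interior local maxima with
  prominence at least 5 % of the smoothed curve's range count as distinct
  scales. Prominence is relative, so detection is invariant to uniform
  scaling of the statistic. A maximum at the smallest grid radius is
  reported separately as the resting-stop signature (the curve "peaking
  at $r \to 0$") and never counted as an ARS scale. The 5 % threshold is
  this package's operationalisation of "distinct versus shallow" — no
  quantitative rule exists in the literature — and both knobs are
  exposed and archived in the run configuration.
* **Upper-limit radius rule**: when several peaks fall within a factor
  of two of each other they are treated as one scale domain and the
  largest radius represents it. Under-estimating the radius is the more
  dangerous error (it splits single visits into spurious revisits), so
  the upper limit of a domain's range is the safer analysis radius. The
  factor-two grouping is this package's operationalisation; it is
  exposed as `domain_factor`.
* The unbiased ($n-1$) sample variance is used throughout.

## The simulation world

`generate_resource_map()` and `simulate_forager()` provide the
validation world: point food items on a $1{,}000 \times 1{,}000$ cell
grid in three spatial structures (scattered; patchy — items around
random patch centres; two-level hierarchical — patches around clump
centres), and a biased correlated random walk forager. Headings follow

$$\theta_t \sim \mathcal{N}(\theta_{t-1},\, v), \qquad
  v = v_b\,(1 \mp p \cos(\theta_{t-1} - \omega_{t-1})),$$

with step length one cell, basic variance $v_b$, attraction $p \in
[0, 1]$ toward the bearing $\omega$ of a target (minus sign; plus for
repulsion), and reflecting walls. Three strategies: simple search
($p = 0$ throughout, opportunistic consumption within the perceptual
range); simple ARS (on a find, switch to a tortuous attraction walk
anchored on the running centroid of the bout's finds, abandoning after
`giving_up_time_patch` fruitless steps); hierarchical ARS (as simple
ARS, plus out-and-back forays radiating from a departed patch with
geometrically growing legs until a new find or `giving_up_time_clump`
fruitless steps). Consumed items re-emerge after `regeneration_delay`
steps. Exploration is punctuated by brief rest bouts — without them a
searching path never shows the elevated small-radius variance that
stationary stops cause in real data. Every simulation returns a
ground-truth log (per-step behavioural mode, consumption events, ARS
episodes per patch), which the validation suite uses as its oracle.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `n_steps` | 60,000 | study-scale path length; resampled 1-in-10 to mimic GPS sampling (6,000 fixes) |
| `v_b` | 0.03 rad² | near-ballistic exploration: persistence ≫ patch diameter, so en-route residence times are short and uniform, and the forager leaves a clump's neighbourhood rather than re-encountering its patches by diffusion |
| `v_b_ars` | 0.5 rad² | tortuous in-patch search whose loops, anchored on the bout centroid, sweep an area matching the planted patch (items at distance ~10 ± 3 cells) |
| `p` | 0.8 | strong but not absolute attraction during ARS |
| `perceptual_range` | 2 cells | detection/consumption radius |
| `giving_up_time_patch` | 250 steps | long enough that a patch is largely depleted per visit (bout length ≈ 400–700 steps, ~10–14 items), so visits dominate passage times |
| `giving_up_time_clump` | 1,500 steps | several foray cycles before abandoning a clump, while still forcing clump turnover within a run |
| `foray_leg0`, `foray_growth` | 60 cells, ×1.3 | first legs reach the typical within-clump patch separation; growth radiates outward |
| `rest_prob`, `rest_mean` | 0.004/step, 30 steps | brief, frequent rests (~10 % of exploring time), strong enough to mark the smallest radii without rivalling patch visits |
| patchy maps | 30 patches, 20 ± 5 items at 10 ± 3 cells | ~600 items; patch footprint radius ~13–19 cells |
| hierarchical maps | 5 clumps, 5 ± 1 patches at 160 ± 40 cells | patch and clump scales ~12× apart, so both peaks are resolvable on a log grid |
| `regeneration_delay` | 10,000 steps | slow enough that clumps deplete and force movement between clumps, fast enough that patches are revisited within a run |

These values were calibrated once against path-regime diagnostics — ARS
step fraction, bout length relative to crossing time, per-bout
depletion, multi-clump use — and then frozen; the validation batteries
run against these defaults.

### What the generator does and does not emulate

It emulates: discrete food encounters, giving-up-time patch leaving,
nested spatial structure, depletion with delayed renewal, resting, and
GPS-like subsampling of a continuous path. It does not emulate: location
error, irregular fix intervals or gaps (the analysis accepts them; the
generator does not produce them), memory or knowledge-based returns,
energetic state, conspecifics or predators, heterogeneous movement
costs. Passing validation on this world therefore shows that the
statistics recover planted structure under the model's own assumptions —
not that they are robust to telemetry error or behaviours outside the
model.

## Validation and known limitations

The test suite (`tests/testthat/`) validates the geometry kernels
against dense re-discretisation oracles refined by bisection, the graph
step against a union-find oracle, and the full pipeline against
scripted trajectories with hand-countable visit structure. The
acceptance battery re-runs the study design at full scale: 30
simulations per scenario, each 60,000 steps resampled 1-in-10, with all
defaults. With `scripts/acceptance.R` the same batteries are re-run from
a command-line seed.

Known limitations, visible in those batteries:

* **Flat-curve noise.** A pure searching path has a low-amplitude curve,
  and because peak prominence is judged relative to the curve's range,
  broad sampling undulations on such curves occasionally clear the 5 %
  threshold. About half of simple-search runs show one such spurious
  shallow "peak"; the resting-stop maximum at the smallest radius is,
  however, present essentially always and correctly excluded from the
  ARS count.
* **Clump-scale shoulders.** For the hierarchical forager the
  clump-scale signal rides the right tail of the much stronger
  patch-scale peak. In roughly half of the runs it forms a genuine local
  maximum and is detected; in the rest it remains a shoulder below the
  prominence threshold. Multiscale detection is therefore reliable in
  aggregate (multi-peak curves essentially never occur for single-scale
  strategies) but not run-by-run.
* **Place recovery is conservative.** The filtering threshold
  (max of mean and median) is driven up by the strongest bouts, so
  weakly revisited patches are missed, and representatives of detected
  places sit inside the planted patch footprint in most but not all
  detections (ARS loops overshoot the outermost items). The recovery
  rates computed in the acceptance battery fall short of ideal recovery;
  the same mechanisms — conservative filtering, merged neighbours,
  stopping-site detections — are the error modes the place diagnostics
  (`single_visit`, `oversized`) are designed to surface.

## Sensitivity knobs worth knowing

* `max_time_outside` extends residence times across brief excursions;
  use it when the analysis radius must sit below the true ARS radius,
  and prefer a radius at the upper limit of the detected domain
  otherwise.
* `criterion = "total_time"` highlights frequently revisited sites at
  the cost of overlooking places with one or two long visits; run both
  criteria and compare when the study question is not purely ARS
  detection.
* The framework is not a home-range estimator: at radii large relative
  to the occurrence area, circles lose meaning and utilisation
  distributions are the right tool.
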