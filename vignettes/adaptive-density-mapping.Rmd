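---
title: "Adaptive sampling and kernel density mapping of app-user populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive sampling and kernel density mapping of app-user populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(appdens)
```

## The measurement model

Geosocial networking apps rank nearby profiles by linear distance from
the observer, without direction. A field observer at a stop therefore
sees a censored snapshot of the local point pattern: the `k = 50`
nearest users, or all users within a maximum radius `r_max = 2` miles,
whichever is fewer. Two quantities come out of each stop:

* the capture count `n` for each stratum (race category x age group),
* the observed radius `r` — the distance to the k-th nearest user when
  the stop is over-subscribed, `r_max` otherwise.

Stops with different radii observe different areas, so counts are not
comparable until standardized. We rescale to a 1-mile-radius reference
circle (area pi square miles):

* users per square mile: `n / (pi r^2)`,
* users per reference circle: `n / r^2` (= pi times the per-square-mile
  density).

The observed radius also drives the *adaptive* part of the protocol:
the next stop is placed `r` miles further along the route. Where users
are dense the radius shrinks, stops pack together, and spatial
resolution improves exactly where the signal is strongest; in sparse
areas the protocol falls back to regular 2-mile spacing, and since a
2-mile step is paired with a 2-mile observation radius, consecutive
circles always overlap along the route.

## From stops to surfaces

`kernel_density()` turns the stop table into a raster of users per
square mile. Each stop contributes a radially symmetric kernel centered
at its location, scaled so the kernel's integrated volume equals the
stop's weight. The default weight is the standardized per-circle count
`n / r^2`; a `weight_mode = "raw"` flag weights by the raw count
instead. Both weightings are legitimate readings of how field GIS
workflows combine per-stop counts, so both are provided; standardized
weighting is the default because it is the one that makes stops with
different radii commensurable.

Two kernels are available:

* `gaussian` (default): bivariate normal with standard deviation equal
  to the bandwidth, truncated at 3 bandwidths and renormalized to unit
  mass. The truncation keeps each stop's influence local (99% of an
  untruncated gaussian's mass lies within 3 bandwidths; renormalization
  returns the lost 1.1%), so total surface volume equals total weight
  up to raster discretization. At a stop's own location the surface
  value is `w / (2 pi h^2 (1 - e^{-9/2}))`, about 1.1% above the
  untruncated closed form `w / (2 pi h^2)`.
* `quartic`: `3/(pi h^2) (1 - (d/h)^2)^2` with compact support of one
  bandwidth — the kernel classically used by GIS "kernel density"
  tools, included so surfaces can be compared against that tool
  family's semantics.

Kernels are evaluated at cell centers only; with the default 0.1-mile
cells and bandwidths of 1-2 miles the cell size is at most a quarter
bandwidth and subcell integration error is negligible. Rasters follow
the ESRI ASCII grid convention (row 1 on top, `xllcorner`/`yllcorner`
naming the lower-left corner), and cells outside the study region are
NODATA when a region mask is supplied.

Bandwidth trades interpolation against locality: 1-mile surfaces have
higher peaks and more empty area, 2-mile surfaces spread observations
further and cover the whole region. The package takes no position
beyond exposing the parameter; 2 miles is the default because it
matches the protocol's maximum observation radius.

## Comparing subgroup surfaces

Three map-algebra measures compare co-registered surfaces `A` and `B`
(same grid, checked exactly):

* **difference** `A - B`: null value 0; positive cells have an
  absolute excess of stratum A users.
* **ratio** `A / B`: null value 1; flags *relative* excess even where
  both densities are small. Cells with `B = 0` become NODATA — an
  ASCII raster has no infinity, and a sentinel would poison later
  algebra.
* **indicator difference**
  `I(A > mu_A + 2 s_A) - I(B > mu_B + 2 s_B)`: each surface is
  thresholded against its *own* mean + 2 SD, so the result takes only
  the values {-1, 0, 1} and highlights where each stratum's density is
  extreme for that stratum, regardless of absolute magnitude.

Surface statistics use the population (divide-by-N) standard deviation
over every non-NODATA cell inside the region mask, zeros included —
the raster-statistics convention of the GIS tools this mirrors — and
the threshold uses a strict inequality, so a constant surface (SD 0)
has no extreme cells. Computing the statistics over region-masked
cells only is a deliberate choice: the sample space is the city, not
the rectangular raster that happens to contain it.

## The synthetic population generator

`generate_population()` draws a marked inhomogeneous Poisson pattern:
each `intensity_component()` contributes `Poisson(E)` users scattered
as an isotropic bivariate normal around its center (rejection-sampled
into the region), and per-race background rates add uniform scatter.
Race is a component-level mark; ages come from two-component normal
mixtures truncated at 18 and rounded to years. The defaults in
`default_age_spec()` are calibrated so white users have median age 33
and black users 28. `assign_missingness()` then independently blanks
race (default 5.51%) and age (default 22.24%).

The bundled demo scenario (`demo_region()`, `demo_intensity()`,
`demo_route()`) emulates the pilot city's conditions:

* a 13.24 x 10 mile rectangle (132.4 square miles);
* about 2666 expected users with pre-missingness race mix
  0.6205 / 0.3215 / 0.0580, chosen so the *observed* mix after race
  missingness is 58.6% white / 30.4% black / 5.5% other / 5.5%
  unreported;
* a shared central "Midtown"-like hotspot for both races, a secondary
  white cluster to the northeast, the main black cluster to the
  southwest, and uniform other-race background — strong spatial
  segregation with one shared peak;
* a serpentine route with 1.8-mile row spacing. Every region point is
  within 1 mile of the polyline and stops are at most 1 arc-mile from
  any path point, so in sparse areas (2-mile radii) full circle
  coverage of the region is guaranteed by construction. Under the
  demo population the route yields on the order of 80 adaptive stops,
  matching the pilot's 79.

What the generator does *not* emulate: user churn between stops (the
population is frozen during a traversal), day-of-week and time-of-day
variation, GPS measurement error, duplicate profiles across apps, and
road-network constraints beyond the polyline route. Passing tests
therefore demonstrate that the estimator recovers a *known stationary*
intensity under the field protocol — not that any particular app's
user base is stationary.

## Numerical and degenerate-case choices

* **Ties at the k-th distance**: all profiles at exactly the k-th
  distance are captured (captures may exceed `k`); the radius is that
  distance. Deterministic and independent of input order.
* **Coincident users at a stop**: a zero k-th distance would stall the
  route, so the advance is floored at `1e-6` miles.
* **Zero-capture stops** are retained with density 0 — sparse stops
  carry real information.
* **Users seen from overlapping stops** are *not* deduplicated across
  stops; each stop is an independent density observation, mirroring
  per-stop aggregation in the field.
* **Age bins**: right-open, default edges `c(18, 25, 31, Inf)` giving
  18-24 / 25-30 / >30; edges are configurable (e.g.
  `c(18, 26, 31, Inf)` for the 18-25 / 26-30 convention) because both
  groupings occur in practice. Labels derive from the edges.
* **Missing race** is kept as its own mark at generation and collapsed
  to "other" only at analysis-time categorization, so the same
  population supports both raw and analysis views.
* **Determinism**: every stochastic function takes a seed and restores
  the caller's RNG state; the pipeline is a pure function of
  (config, seed), and all writers use canonical `%g` 6-significant-
  digit formatting so file round trips are byte-identical.

## Problem sizes used in the test suite

The bundled checks run the demo scenario at its natural scale: ~2500
users, ~80 stops, a 133 x 101 cell raster at 0.1-mile cells. The
intensity-recovery check compares the estimated 2-mile surface against
the true generating intensity at 200 randomly chosen in-region cells
by Spearman rank correlation; rank correlation is the right yardstick
because kernel smoothing biases absolute levels (peaks flatten,
valleys fill) while preserving ordering. Monte-Carlo checks of the
generator (Poisson counts, race fractions, missingness rates) use a
few hundred replicates, enough to pin means within a few standard
errors without slowing a routine test run.

## Known limitations

* The estimator inherits the protocol's censoring: in over-subscribed
  areas the surface reflects the 50 nearest users, not all users, and
  standardization assumes users are roughly uniform within each stop's
  circle.
* No statistical significance machinery is attached to hotspots; the
  mean + 2 SD rule is descriptive, not a test.
* No kriging or other geostatistical interpolation; kernel smoothing
  only.
* Planar miles throughout: the package deliberately performs no
  lat/lon handling, so inputs must already be in a local planar
  approximation.
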