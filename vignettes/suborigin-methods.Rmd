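---
title: "Tracing Sargassum strandings to oceanic sub-origins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing Sargassum strandings to oceanic sub-origins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sargdrift)
```

## The scientific question

Pelagic *Sargassum* stranding on eastern Caribbean beaches is a mixture of
three morphotypes (*S. natans* I, *S. natans* VIII, *S. fluitans* III)
whose relative abundance varies strongly through the year. One candidate
explanation is that strandings at different times of year arrive from
different oceanic source regions along different transport pathways, and
that conditions along those pathways favour different morphotypes.
`sargdrift` implements the full chain of analysis needed to test this
idea:

1. backtrack each stranding date through a year-day surface-current
   climatology with an ensemble of stochastic particles;
2. reduce each ensemble to trajectory metrics and partition the
   simulations into two sub-origin/transport-pathway groups;
3. test whether three-part morphotype compositions differ between the
   groups with a PERMANOVA under a restricted nested permutation scheme,
   plus a dispersion-homogeneity check;
4. contrast environmental conditions (SST, chlorophyll-a) at the origins
   and trajectory midpoints of the two groups.

Because the real drifter archive and stranding volumes are not shipped
with the package, a synthetic-data module generates every input with a
*planted* two-pathway seasonal structure. All statistical machinery is
exercised end to end against data whose ground truth is known.

## Particle tracking model

Particles are advected with an explicit Euler step of `dt = 21600` s (the
6-hour cadence of drifter records). The total velocity at a particle is

* the bilinearly interpolated climatological current (linear and circular
  in year-day),
* a stochastic turbulence term applied to each component:
  `u' = u + c * s * Z`, where `s` is the current speed, `Z` a standard
  normal draw, and `c = 0.1` by default — acknowledging that a gridded
  climatology is smoother than the real ocean,
* windage: a fixed fraction (0.5% by default) of the 10-m wind vector,
  applied to the unperturbed wind.

Displacements are converted to degrees on a sphere of radius 6371 km:
`dlat = v dt / (R pi/180)` and `dlon = u dt / (R pi/180 cos(lat))`.
Backward tracking integrates the sign-reversed velocity field; no
time-reversed correction of the turbulence is attempted, matching the
simple backtracking construction. Per-particle path length is accumulated
as the haversine distance of every step on the same sphere.

Numerical and policy choices, all configurable:

* **Ensembles** default to 100 particles over a 365-day horizon; each
  ensemble's endpoint cloud is summarized by its centre of mass (the
  arithmetic mean of endpoint longitudes and latitudes — safe away from
  the antimeridian, and guarded by an assertion). Grounded particles are
  included in the centre of mass.
* **Grounding**: a particle whose destination cell is land keeps its last
  ocean position and is frozen for the remainder of the integration, with
  the grounding step recorded. A particle leaving the domain is likewise
  frozen at its last interior position and flagged.
* **Reproducibility**: each simulation draws its turbulence from a seed
  derived by a stable string hash of the collection date and the global
  seed, so studies are bit-reproducible and simulations can be re-run
  independently in any order. (Draws are vectorized across the ensemble
  per step rather than per-particle counter-based.)
* **Reversibility**: with turbulence off, a backward track in a steady
  field retraces forward to within a fraction of a grid cell at the
  default step (the Euler scheme's asymmetry is first order in `dt`).

## The current climatology

`build_climatology()` turns 6-hourly drifter fixes (year, day, hour, lon,
lat, u, v, drogue flag) into a year-day climatology by cell-mean binning:
each cell/year-day receives the mean of all fixes falling in the cell
within a circular ±7-day window. Remaining empty cells are filled by up to
three nearest-neighbour dilation passes, then set to zero with a zero
observation count. The exact reduction used to produce the original
gridded product is not public; cell-mean binning with a configurable
window and fill radius is the simplest defensible estimator, and the
drogue-only filter is exposed because the original product's drogue
policy is unknown. Leap days are stripped (Feb 29 maps to the year-day of
Mar 1) to give exactly 365 year-day slots.

## The synthetic ocean

`generate_current_field()` builds a kinematic test harness, not a
dynamical ocean: a 62°W–30°W, 5°S–22°N domain at 1/4° with

* **Pathway A** (regime A, year-days 60–218 ≈ March–early August): a fast
  meandering jet from a low-latitude (3°N) eastern source, running west
  along a sinusoidal equatorial axis and turning northwest along a
  synthetic coastline to the Barbados-like target. Default net speed
  0.8 m/s (Guiana-current-like).
* **Pathway B** (regime B, the rest of the year): a direct near-zonal jet
  from a 17°N eastern source whose axis approaches the target along a
  square-root curve, so the two corridors separate within a degree or two
  of the launch point. Default net speed 0.2 m/s.
* a weak uniform westward background (0.02 m/s), a constant easterly
  trade wind (−5 m/s) for the windage term, and a land wedge south-west
  of pathway A's axis.

Fields switch regime by a smooth 10-day cross-fade at calendar boundaries
to avoid velocity discontinuities. Two constructional details matter for
faithful routing: the jets' meridional component carries a `1/cos(lat)`
factor so that particle motion parallels the axis in lon/lat space, and
the jet core compensates the ambient westward drift (background plus
windage), i.e. *jet speeds are specified as the net drift speed of
floating material*. Without these, discretization-scale drifts slowly
push particles off the jet and the planted structure degrades.

Jet speeds are free parameters — no observed current speeds are imposed
anywhere — chosen once by transit-time arithmetic: a 365-day backtrack
spends about 158 days exposed to regime-A fields and 207 days to regime-B
fields, and the default speeds let each pathway traverse most of its
(~4900 km and ~3300 km) course in that exposure. The resulting contrast
(pathway A: long distances, equatorial origins; pathway B: shorter direct
routes, 15–17°N origins) reproduces the qualitative structure of observed
backtracks.

**What the emulation does not contain**: eddies, divergent flow,
Stokes drift, inertial oscillations, interannual variability, or a
dynamically balanced velocity field. Passing the recovery tests shows the
*pipeline* can detect a two-pathway seasonal structure when one exists;
it does not validate the oceanography of any particular year.

A known and deliberate feature: collection dates falling within a few
days after a regime boundary have genuinely mixed backtrack provenance
(their 365-day history samples both regimes near the launch point), and
the default 5th-of-March date is typically attributed to the "wrong"
cluster for exactly this reason. Recovery of the planted regime therefore
plateaus near 96%, not 100% — which is the scientifically honest
behaviour, and mirrors the manual attribution ambiguity of transition
dates in real campaigns.

## Morphotype compositions

Clump volumes are Dirichlet-distributed: for a date in regime `r`, each
of 3 clumps draws a composition from `Dirichlet(conc * mean_r)` and
scales it by a Gamma-distributed total volume (~250 mL). The default
means, `A = (0.10, 0.15, 0.75)` and `B = (0.08, 0.55, 0.37)` in the order
(SNI, SNVIII, SFIII), plant the observed contrast — *S. fluitans* III
dominance on pathway A, elevated *S. natans* VIII on pathway B — with
concentration 30 giving realistic clump-to-clump scatter. These means are
free parameters of the emulation, not measured values.

Analysis follows the compositional-data canon for three parts:

* relative abundance = volume / total volume per clump;
* aggregation first by date, then by month, with arithmetic means and
  re-normalization at each stage (each date weighs equally in its month
  regardless of clump count);
* an isometric log-ratio transform to two unconstrained coordinates,
  `z1 = ln(p1/p2)/sqrt(2)`, `z2 = sqrt(2/3) ln(sqrt(p1 p2)/p3)`, removing
  the unit-sum dependence; zeros are first replaced multiplicatively at
  0.005. The transform is a bijection (inverse provided and tested to
  1e-9);
* ternary coordinates for display, with vertices (SNI, SNVIII, SFIII) at
  (0,0), (1,0) and (1/2, sqrt(3)/2).

## PERMANOVA with restricted nested permutations

The central test asks whether clump compositions differ between
sub-origins, while respecting that clumps collected the same date are
pseudo-replicates: dates, not clumps, are the independent units. The
pseudo-F is the distance-based one-factor partition (Euclidean distances
between log-ratio coordinates; equivalent to the Gower-centred
hat-matrix partition for this design), and the null distribution permutes
*whole dates* between sub-origins, preserving observed group sizes, with
samples travelling with their date. p-values use the add-one rule
`p = (#\{F_perm >= F_obs\} + 1) / (n_perm + 1)`; an exhaustive mode
enumerates all distinct date-label assignments when wanted. Euclidean
distance is the appropriate choice on log-ratio coordinates (they are
real-valued and may be negative; rank-based ecological dissimilarities
are not meaningful there). Defaults: 9999 permutations, significance
0.05, no multiple-testing correction (a handful of planned tests).

Validation in the test suite: agreement with exhaustive enumeration on
six dates (20 assignments); exact type-I error (rejection rate within
[0.035, 0.065] over 1000 null replicates); equality with a standard
one-factor PERMANOVA when every sample is its own date, cross-checked
against an independent reference implementation.

Dispersion homogeneity is checked in the betadisper style: principal
coordinates of the distance matrix, each point's distance to its own
group centroid (centroids, not spatial medians), a one-way F on those
distances, and significance by freely permuting the distances across
groups.

## Environmental contrasts

For each simulation, SST and chlorophyll-a are averaged over a square box
of ~93,500 km² (side 305.78 km, converted to degrees at the centre
latitude with 111.32 km/degree) centred (1) on the centre-of-mass origin
at the collection date minus 365 days and (2) on the ensemble mean
position 183 backtracked days along the track, at the date minus 183
days, using the 8-day composite nearest the target date. The synthetic
fields provide 46 composites per year with a monotone equatorward SST
gradient and near-coast chlorophyll enhancement, so pathway A (equatorial
origins) is systematically warmer — the direction the pipeline should
recover.

The two-factor test uses the bivariate response (SST, sqrt-chl), each
column z-scored (°C and mg m⁻³ are incommensurable under Euclidean
distance; scaling is configurable), sequential (Type I) sums of squares
for period, sub-origin and their interaction via hat-matrix projections
of the Gower-centred inner-product matrix, and free row permutations per
term. The square-root transform tames extreme chlorophyll values.

## Problem sizes and defaults

The shipped defaults are the study conditions: 24 collection dates (two
per month), 100 particles per ensemble, 365-day horizons, 1/4° grids, 46
environmental composites, 3 clumps per date, 9999 permutations for
reported tests (999 inside the test suite's replicated simulations). The
forward dispersal experiment seeds 200 particles in a bloom-region-like
box (45–32°W, 0–8°N) and reports the retention curve and the first day at
which 90% have dispersed.

## Known limitations

* The synthetic velocity field is kinematic; distances and origin
  positions are meaningful only relative to the planted structure, not as
  predictions for any real year.
* Backward integration of a diffusive ocean is ill-posed in principle;
  as in the original methodology, the ensemble spread under the
  stochastic turbulence model is the uncertainty proxy.
* The centre-of-mass origin can fall in a region no single particle
  visited if the endpoint cloud is multimodal.
* K-means with k = 2 on (mean distance, origin latitude) is a pragmatic
  classifier; trajectory-shape clustering is out of scope.
* Dates shortly after a regime boundary are intrinsically ambiguous (see
  above); with only one year of (synthetic) sampling, no claim about
  interannual stability is possible.
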