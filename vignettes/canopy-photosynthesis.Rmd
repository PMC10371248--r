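---
title: "Modelling canopy photosynthesis from 3D plant architecture"
author: "canophot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling canopy photosynthesis from 3D plant architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canophot)
```

## The problem

Canopy photosynthesis (`A_c`, umol CO2 per m2 of ground per second) emerges
from the interaction of three trait groups that breeders can select on
largely independently: plant architecture (which controls how light is
distributed over the foliage), leaf optical properties (reflectance `R` and
transmittance `T`, largely set by chlorophyll content), and the leaf
photosynthetic light response. Because the traits interact -- an
architecture that spreads light more evenly changes the marginal value of a
higher photosynthetic capacity -- their contributions cannot be read off
one-factor experiments. canophot implements a simulation pipeline that
makes the decomposition explicit: build 3D canopies in which each trait
group can be swapped between two varieties, compute daily canopy CO2
uptake (`A_c,d`) for every combination, and attribute the difference
between the varieties to main effects and interactions by
inclusion-exclusion.

The pipeline has five stages, each usable on its own:

1. **Point clouds** (`labeled_point_cloud`, `remove_ground_plane`,
   `denoise`): pre-segmented single-plant clouds (each point labelled stem
   or leaf-k) are cleaned by robust ground-plane removal, Euclidean
   clustering, and a statistical kNN-distance outlier filter.
2. **Leaf vector models** (`extract_vector_model`,
   `generate_synthetic_plant`): each leaf is reduced to an editable
   skeleton -- a midrib axis polyline plus per-station half-width vectors
   -- either extracted from a cloud or generated parametrically.
3. **Meshing and canopy assembly** (`mesh_plant`, `build_canopy`): vector
   models are lofted into triangle meshes and replicated over a row grid
   (default 4 rows x 13 plants, 55 cm x 15 cm spacing) with a central
   110 cm x 75 cm scoring region that excludes border plants.
4. **Light** (`solar_position`, `incident_ppfd`, `trace`,
   `diurnal_trace`): hourly direct and diffuse photosynthetic photon flux
   is propagated through the canopy by Monte-Carlo ray tracing, yielding
   absorbed PPFD per leaf facet.
5. **Photosynthesis and dissection** (`leaf_A`, `canopy_A`,
   `diurnal_canopy_A`, `run_dissection`, `sweep_photosynthesis`,
   `sweep_architecture`): facet-level assimilation is integrated to
   `A_c,d` and dissected factorially.

## The leaf model

Leaf net assimilation follows the non-rectangular hyperbola: `A` is the
lower root of

    theta * A'^2 - (phi * I + Pmax) * A' + phi * I * Pmax = 0,   A = A' - Rd

with capacity `Pmax` (umol m-2 s-1), initial quantum yield `phi` (mol CO2
per mol photons), convexity `theta` in (0, 1], and dark respiration `Rd`.
`theta = 0` degenerates to the rectangular hyperbola, `theta -> 1` to the
Blackman limiting-factor response; both limits are handled explicitly.
`fit_light_response()` estimates the four parameters from measured
light-response curves by bounded Levenberg-Marquardt least squares, with
`Rd` initialised from the dark point, `phi` from the low-light slope and
`Pmax` from the plateau. Canopies carry two parameter sets -- up-layer and
bottom-layer leaves (split at the plant's mid-height) -- and no further
within-layer gradient; this mirrors how such data are usually measured and
is a stated scope limit, not an oversight.

Facet assimilation is driven by the facet's *absorbed* PPFD, since the ray
tracer already applies the leaf absorptance `1 - R - T`; a
`ppfd_basis = "incident"` interpretation can be emulated by tracing with
black leaves.

### Identifiability of the light-response fit

A single 12-level curve with additive noise of sd 0.5 umol m-2 s-1
identifies `Pmax` and `phi` well (their median bias across replicate fits
is a fraction of a percent; see the test suite), but `Rd` and `theta` only
loosely: the Fisher information of this design puts the standard error of
`Rd` near 0.4 umol m-2 s-1 -- more than 20% of a typical maize value --
and that of `theta` near 0.07. No fitting algorithm can beat these bounds;
joint recovery of all four parameters to within 10% is therefore rare at
this noise level, and the test suite records that fact rather than hiding
it. In practice one fits replicate-averaged curves, for which the bounds
shrink with the square root of the replicate count.

## Light environment

Hourly solar geometry uses the standard declination series and hour-angle
formulation (hours are local solar time). Clear-sky irradiance uses an
extraterrestrial PAR constant of 1367 W m-2 x 0.45 (PAR fraction)
x 4.57 umol J-1 ~= 2811 umol m-2 s-1 on a beam-normal plane, attenuated by
`tau^m` with air mass `m = 1/cos(zenith)` and atmospheric transmittance
`tau = 0.7` by default; half of the scattered flux reaches the ground as
diffuse sky light. These constants are arguments, not hard-coded, because
the partition formula is a modelling choice the incident-light literature
does not fix uniquely; everything downstream sees only the resulting
direct/diffuse horizontal PPFD pair.

Leaf optics come either from spectra (PAR-band averages weighted by the
incident spectrum, plain sums over 400-700 nm) or from SPAD chlorophyll
readings through empirical percent-valued regressions (a shared quadratic
for transmittance; variety-specific reflectance models). Note that the
transmittance quadratic reaches its minimum near SPAD 65; above that,
absorptance no longer grows with chlorophyll reading.

## Ray tracing

`trace()` is a forward Monte-Carlo tracer over the flattened canopy mesh:

* the direct beam is launched from a stratified-jittered grid on the top
  plane along the solar direction; diffuse sky light from cosine-weighted
  downward directions (uniform overcast -- the sky radiance distribution
  is a config-isolated choice);
* on a facet hit, `1 - R - T` of the ray power is scored as absorbed;
  survival is single-ray Russian roulette (reflect with probability `R`,
  transmit with `T`, terminate otherwise) with Lambertian redistribution,
  which keeps the estimator unbiased without spawning ray trees;
* lateral boundaries are periodic, so a small scene behaves like an
  infinite field; the default layout additionally keeps guard rows and
  scores only the central region, so edge treatment never touches the
  reported fluxes; the ground absorbs; paths are capped at 5 bounces
  (with `R + T ~ 0.15` the truncated energy is of order `0.15^5`);
* a uniform voxel grid accelerates intersection; every ray owns a
  counter-seeded RNG stream, so results are bit-reproducible for a fixed
  seed regardless of scheduling.

Facets are scored on both sides and absorbed flux is expressed per unit
one-sided facet area, consistent with one-sided leaf area elsewhere.
Energy closure (emitted = absorbed + ground + escaped) holds to well under
0.5% at a million rays, and interception of a homogeneous random black
canopy reproduces the turbid-medium law `1 - exp(-0.5 LAI)` for a
spherical leaf angle distribution within a few percent.

## Trait adjustments

`trait_adjustment()` edits vector models directly: length and width scale
multiplicatively (axis about the leaf base; half-width vectors in place);
insertion angle rotates the whole leaf rigidly about the horizontal axis
through its base; curvature is distributed progressively along the axis so
the tangent turns by exactly the requested angle between base and tip.
Sign conventions -- positive angle delta = more erect, positive curvature
delta = droopier -- are package conventions (the trait definitions do not
fix a sign) and are documented on the function. Leaf-number increases
clone leaves cycled from the top of the plant, rotated 180 degrees in
phyllotaxis and stacked above the current top at the plant's mean
internode spacing, preserving the light-dominating upper canopy; decreases
remove leaves from the bottom up. Layers are re-derived after leaf-number
changes.

## Synthetic plants

`generate_synthetic_plant()` provides the test bed: maize-like plants with
alternating phyllotaxis, an insertion angle from the vertical, progressive
droop along the blade, and a blade-width profile that is ~55% of maximum
at the collar (real blades emerge wide from the sheath), widest near 40%
of the length, and tapering to the tip. Two contrasting presets span the
architectures of interest -- `erect` (12 leaves, 45-70 cm, ~22 degrees
from vertical) and `spread` (10 leaves, 55-88 cm, ~52 degrees, strong
droop) -- plus `toy-flat` for analytic checks. Jitter magnitudes (5%
length, 4-5 degrees angle, 12 degrees azimuth) are fixed, seeded draws.

What the generator does *not* emulate: blade twist and waviness, sheaths,
tassels, senescent tissue, and measurement artefacts of real
structure-from-motion clouds (holes, ghost points, registration error
beyond isotropic jitter). Passing round-trip tests on these clouds
therefore demonstrates correctness of the extraction machinery, not
instrument-grade accuracy on field data. The round-trip test samples
surfaces at ~1-3 mm spacing with 1 mm isotropic noise, the density class
of multi-view-stereo reconstructions; at much coarser sampling the
sparsely sampled blade tip shortens extracted lengths by a further
percent or two.

## Factorial dissection

`run_dissection()` builds the eight canopies that combine architecture
(S), leaf photosynthesis (P) and chlorophyll-derived optics (C) from a
base and a donor bundle, and derives contributions:

    c(S)  = A(S) - A(O)                      (main effects, likewise P, C)
    c(SP) = A(SP) - A(S) - A(P) + A(O)       (pairwise, likewise SC, PC)
    c(SPC) = A(SPC) - A(SP) - A(SC) - A(PC) + A(S) + A(P) + A(C) - A(O)

so that `A(SPC) - A(O)` equals the sum of all seven terms identically.
All eight scenarios within one replicate share one RNG seed; the Monte
Carlo noise of the ray tracer then differences out of the contrasts, and
the inclusion-exclusion identity holds to floating-point precision per
replicate. Replicates vary both plant placement and ray seeds (each
switchable). Relative contributions are expressed as percent of the base
scenario `A_cd(O)`.

The sensitivity sweeps reuse machinery: photosynthetic-parameter sweeps
re-trace nothing (geometry and optics are unchanged, so hourly absorption
fields are cached and only the leaf response is re-evaluated), while
architectural sweeps re-mesh and re-trace per value and report LAI
alongside `A_c,d`, enabling LAI-mediated comparisons of width, length and
leaf-number effects.

## Numerical choices and degenerate inputs

* Geometry is in centimetres, Z up, ground at z = 0; areas convert to m2
  only in LAI and flux reporting.
* Leaf axes carry 31 stations by default; doubling stations changes
  lofted areas by well under 0.5%, and degenerate facets (area < 1e-4
  cm2, aspect ratio > 100) are dropped during meshing.
* The statistical denoise filter implements the conventional
  mean-plus-k-standard-deviations cut on the mean distance to the 50
  nearest neighbours with k = 0.3. That cut necessarily trims the upper
  tail of any continuous distance distribution (including the elevated
  statistics of blade-edge points), so exact idempotence and "no clean
  points removed" hold only for clouds whose statistic is homogeneous;
  the filter is kept in this classical form deliberately and its
  behaviour is characterised, not patched, in the tests.
* Ground-plane removal is RANSAC with a least-squares refit on the
  inliers and a fixed, caller-supplied seed.
* The leaf-extraction geodesic can drift from the midrib toward a blade
  edge; one midrib re-centring pass (stations moved to the midpoint
  between detected edges, then re-cut) and near-extreme quantile edge
  detection (0.5%/99.5%) remove the resulting width inflation.
* Fits that cannot converge (constant data, degenerate responses) return
  a flagged result rather than throwing.

## Problem sizes

Unit tests run canopies of one to ten plants at 500-4000 rays per m2 and
two to three daylight hours; the acceptance script runs the full 4 x 13
layout, hourly from 05:00 to 20:00, at 1500 rays per m2 with two
replicates, and the energy-closure check at one million rays. These sizes
were chosen so the whole suite characterises every claim in minutes on a
single core while keeping Monte-Carlo noise far below every asserted
tolerance; all of them scale linearly in rays and facets if more precision
is wanted.

## Worked example

```{r, eval = FALSE}
library(canophot)

plants <- lapply(1:4, function(i)
  generate_synthetic_plant(architecture_preset("erect"), rng_seed = i))
scene <- build_canopy(lapply(plants, mesh_plant), canopy_layout(),
                      rng_seed = 1)
compute_lai(scene)

absorption <- diurnal_trace(
  scene, day = list(date = "2020-08-27", latitude = 30.93),
  optics = spad_to_optics(55, "W64A"), hours = 5:20, rays_per_m2 = 5000)
daily <- diurnal_canopy_A(absorption, default_photosynthesis_params(),
                          scene)
daily$A_cd     # mol CO2 m-2 ground day-1
```

## Known limitations

* Optics are PAR-broadband; no spectral tracing, specular reflection or
  penumbra.
* No Farquhar-type biochemistry, stomatal or temperature response; the
  NRH parameters are phenomenological and hourly-constant.
* The incident-light model is a clear-sky stand-in behind a narrow
  interface; measured hourly PPFD can be substituted by constructing
  `SkyCondition` objects directly.
* Organ segmentation of raw clouds is out of scope: the reader consumes
  pre-labelled clouds, and the synthetic generator emits labels.
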