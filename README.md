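# canophot

Functional-structural simulation of canopy photosynthesis for maize-like
row crops, built for dissecting **which traits make one variety's canopy
fix more CO2 than another's**: plant architecture, leaf optical
properties (chlorophyll-driven reflectance/transmittance), or the leaf
photosynthetic light response — and how strongly they interact.

The package covers the full chain:

* **Labelled point clouds** — PLY/XYZ input with per-point organ labels,
  RANSAC ground-plane removal, Euclidean clustering and statistical
  kNN-distance denoising.
* **Leaf vector models** — each leaf as a midrib axis plus per-station
  half-width vectors, extracted from clouds (graph geodesic + cutting
  planes) or generated parametrically; editable leaf length, width,
  number, curvature and insertion angle.
* **Meshing and canopy assembly** — lofted triangle meshes replicated on
  a 4 × 13 row grid (55/15 cm spacings) with a central 110 × 75 cm
  scoring region.
* **Monte-Carlo ray tracing** (C++ core) — hourly direct + diffuse PAR,
  Lambertian leaf scattering by Russian roulette, periodic lateral
  boundaries, per-facet absorbed PPFD; bit-reproducible for a fixed seed.
* **Photosynthesis** — the non-rectangular hyperbola

  `A = [phi*I + Pmax - sqrt((phi*I + Pmax)^2 - 4*theta*phi*I*Pmax)] / (2*theta) - Rd`

  per facet, with curve fitting from gas-exchange data, layer-specific
  parameters, and hourly-to-daily integration to `A_c,d`
  (mol CO2 m⁻² ground day⁻¹).
* **Factorial dissection** — the 8-scenario inclusion–exclusion design
  over architecture (S), photosynthesis (P) and chlorophyll/optics (C),
  `c(S) = A(S) − A(O)` … `c(SPC)`, plus sensitivity sweeps of every
  photosynthetic parameter (×0.6–1.4) and architectural trait
  (LW/LL ×0.6–2.0, LN −4…+8, LC ±180°, LA −20…40°).

SPAD chlorophyll readings convert to PAR-band optics through empirical
regressions (e.g. transmittance `t% = 0.006319·SPAD² − 0.8241·SPAD +
29.49`).

## Worked example

```r
library(canophot)

plants <- lapply(1:4, function(i)
  generate_synthetic_plant(architecture_preset("erect"), rng_seed = i))
scene <- build_canopy(lapply(plants, mesh_plant), canopy_layout(),
                      rng_seed = 1)
scene
#> CanopyScene: 52 instances (10 scored), 4 distinct plants, LAI 5.11

absorption <- diurnal_trace(
  scene, day = list(date = "2020-08-27", latitude = 30.93),
  optics = spad_to_optics(55, "W64A"), hours = 5:20, rays_per_m2 = 3000)
daily <- diurnal_canopy_A(absorption, default_photosynthesis_params(), scene)
round(daily$A_cd, 4)
#> [1] 0.7144
```

`0.7144` is the daily canopy CO2 uptake in mol m⁻² ground day⁻¹ for this
synthetic erect-architecture canopy (LAI 5.11) on a clear late-August day
at 30.9° N; the hourly table in `daily$hourly` shows the expected diurnal
course (negative around dawn/dusk when respiration dominates, peaking
near 22.5 µmol m⁻² s⁻¹ at solar noon).

To dissect a variety difference, wrap each variety's plants, fitted
light-response parameters and SPAD value in `variety_bundle()` and call
`run_dissection(base, donor, dissect_config(), replicates = 5)`; the
result holds `A_c,d` for all 8 scenarios and the seven contributions in
absolute and percent terms.

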