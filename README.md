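# svatdrought

Forest water-balance simulation and physiological drought indices in R.

`svatdrought` is for ecohydrologists who want to quantify *physiological*
drought — the water stress trees actually experience — rather than
meteorological drought. It implements a complete, testable
soil–vegetation–atmosphere-transport (SVAT) pipeline:

* **Soil hydraulics** — Mualem–van Genuchten retention and conductivity
  curves, pedotransfer functions (a KA5-texture-class table and a
  continuous regression, both shipped as clearly labelled synthetic
  surrogate coefficient sets), plant-available water capacity
  (AWC, −6.3 to −1585 kPa) and gravitational storage (GWC) with
  Monte-Carlo uncertainty propagation.
* **Daily water balance** — Rutter interception, degree-day snow,
  Shuttleworth–Wallace two-source potential evaporation, supply-limited
  transpiration with per-layer root water uptake (beta root
  distribution, rhizosphere + plant resistances, critical leaf water
  potential `psicr`), moisture-limited soil evaporation, macropore
  infiltration and an implicit mass-conservative Richards-equation
  solver (compiled core; daily closure < 1e−6 mm).
* **Calibration** — GLUE-style Monte-Carlo filtering against
  depth-resolved soil matric potential sensors with truncated valid
  range (−9 to −1000 kPa): NSE and KGE per depth combined into the
  objective `cof = sqrt(sum_i (1−NSE_i)² + (1−KGE_i)²)`, behavioural
  selection of the best *k* runs, Kolmogorov–Smirnov `D_max`
  sensitivity screening, posterior medians, temporal-split validation.
* **Drought indices** — transpiration deficit `Td = Tp − Ta`, `Ta/Tp`,
  available-water deficit (ADEF), relative plant-available water
  (RELAWAT), rooting-zone matric potential, pF conversion, annual
  budgets per tree type.
* **Synthetic sites** — a weather generator, soil-profile templates and
  virtual noisy/censored sensors from known-truth runs, so the whole
  chain — including parameter recovery — is verifiable without any
  field data.

See the methods vignette
(`vignettes/forest-water-balance-methods.Rmd`) for the model equations,
parameter semantics, numerical choices and limitations.

## Worked example

Storage capacity of a worked one-horizon profile (1 m loam, 20% gravel,
retention parameters θr 0.05, θs 0.45, α 0.01 hPa⁻¹, n 1.5):

```r
library(svatdrought)

profile <- data.frame(top_m = 0, bottom_m = 1, sand_pct = 40, silt_pct = 40,
                      clay_pct = 20, gravel_frac = 0.2, bd_gcm3 = 1.4,
                      corg_pct = 1)
p <- mvg_params(theta_r = 0.05, theta_s = 0.45, alpha = 0.01, n = 1.5,
                ksat = 100)
storage_capacity(profile, list(p), depth_limit = 1)
#> $awc  254.1294   $gwc  40.45717   (mm)
```

254 mm is the water held between field capacity (−6.3 kPa) and the
wilting point (−1585 kPa) over 1 m of fine earth (80% of the volume).

A dry synthetic site (≈540 mm/yr) under a shallow-rooted stand
(`betaroot` 0.92, rooting depth 0.6 m); the first simulated year is
spin-up:

```r
meteo  <- gen_meteo(climate_spec(), n_years = 3, seed = 1, precip_scale = 0.6)
soil   <- gen_profile("deep_loam", seed = 1)
site   <- list(lat = 47, elevation = 600, slope = 0, aspect = 180,
               tree_type = "deciduous", height = 25, maxlai = 4.6)
column <- soil_column(soil, apply_ptf(soil, "wessolek"),
                      betaroot = 0.92, maxrootdepth = 0.6)
run <- run_simulation(meteo, site, column = column, spinup_years = 1)

ab <- annual_budget(run$fluxes[!run$fluxes$spinup, ], tree_type = "shallow")
ab$budget
#>  year   P   F ETa  Ta  Tp  Td Es Esn Ei
#>  2014 561 119 475 309 374  65 85  40 42
#>  2015 518  90 454 276 394 118 78  57 43
```

Annual transpiration deficits of 65 and 118 mm: the stand reduced its
potential transpiration by 17% and 30% in the two dry years. The
monthly drought indices show the summer drydown:

```r
drought_index_series(run)[6:9, ]
#>   period ta_tp ta_tp_min_daily td_mm relawat psi_rootzone_kpa
#>  2014-06  0.85            0.26    15    0.27             -129
#>  2014-07  0.80            0.21    17    0.59             -124
#>  2014-08  0.81            0.17    18    0.15             -215
#>  2014-09  0.52            0.14    15    0.44             -409
```

By September the rooting zone has dried to −409 kPa (pF 3.6), the
plant-available pool of the rooted layers is low, and on the worst day
actual transpiration falls to 14% of demand. Re-running with deep roots
(`betaroot = 0.98, maxrootdepth = 1.6`) makes the deficit almost vanish
(Td 0 and 11 mm) — the rooting-depth buffering mechanism that separates
shallow- and deep-rooted stands under drought.

Every simulation closes its water balance to numerical precision:

```r
max(abs(mass_balance(run)))
#> 9.99e-10   # mm/day
```

Calibration against (virtual or real) sensors:

```r
obs <- gen_observations(run, sensor_spec(), seed = 2)   # or read_obs_csv()
cal <- calibrate_site(meteo, site, soil, apply_ptf(soil, "wessolek"),
                      obs, n = 500, k = 10, seed = 3)
cal$posterior      # behavioural median parameter set
cal$sensitivity    # D_max per parameter
```

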