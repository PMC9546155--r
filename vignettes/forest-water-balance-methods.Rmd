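---
title: "Modelling forest water balance and physiological drought with svatdrought"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling forest water balance and physiological drought with svatdrought}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svatdrought)
```

# What the package models

`svatdrought` is a soil–vegetation–atmosphere-transport (SVAT) pipeline
for forest drought analysis. A one-dimensional soil column, parameterized
through pedotransfer functions, is coupled to a big-leaf canopy: daily
meteorology drives potential evaporation, a supply function on the
soil-to-leaf pathway limits actual transpiration, and the Richards
equation redistributes soil water. Physiological drought is then
quantified from the simulated state: the transpiration deficit
$T_d = T_p - T_a$, the ratio $T_a/T_p$, the available-water deficit in the
root zone (ADEF), the relative plant-available water in rooted layers
(RELAWAT), and the mean rooting-zone matric potential.

The pipeline is designed to be calibrated GLUE-style against
depth-resolved soil matric potential sensors whose valid range is
truncated (−9 to −1000 kPa for the dielectric probes the data model
emulates), and it ships a synthetic-site generator so that every stage —
including the full Monte-Carlo-filtering calibration — can be exercised
and verified against a known truth without any external data.

# Soil hydraulics

Water retention and conductivity follow the Mualem–van Genuchten model,
with matric potential $\psi$ in kPa (negative) and $\alpha$ per hPa
(1 kPa = 10 hPa):

$$\theta(\psi) = \theta_r + (\theta_s-\theta_r)\,
  \bigl[1+(\alpha\,|h|)^n\bigr]^{-m}, \quad m = 1-1/n,$$

$$K(\psi) = K_s\, S_e^{\tau}\,
  \bigl[1-(1-S_e^{1/m})^m\bigr]^2,$$

with tortuosity $\tau = 0.5$ unless a pedotransfer supplies it. The
plant-available water capacity (AWC) of a profile integrates
$\theta(-6.3\,\mathrm{kPa}) - \theta(-1585\,\mathrm{kPa})$ over depth,
corrected by the gravel fraction; the gravitational pool (GWC) covers
saturation to −6.3 kPa. The pF scale used for plotting and for the sensor
noise model is $\log_{10}$ of $|\psi|$ in hPa.

Two pedotransfer routes are provided:

* `ptf_wessolek()` — a class-keyed table over the German (KA5-style)
  texture classes. `classify_texture()` resolves a sand/silt/clay triple
  deterministically against the shipped class rectangles in the clay–silt
  plane (boundaries belong to the first-listed class).
* `ptf_puhlmann()` — a continuous regression from sand, clay, bulk
  density and organic carbon, with a log10 link for $\alpha$ and $K_s$
  and predictions clipped to physical bounds.

**Provenance of the shipped coefficients.** The original publications'
coefficient tables are not redistributed here. The shipped tables
(`mvg_ka5_synthetic.csv`, `ptf_regression_synthetic.csv`) are synthetic
stand-ins: the regression coefficients were chosen once to reproduce the
qualitative ordering of textural hydraulics (sands drain fast with high
$n$, clays retain with low $n$ and low $K_s$), and the class table was
frozen from the regression evaluated at class-centroid textures. All
calibration machinery treats the PTF prediction as a prior mean and
samples ±30% around it, so the pipeline's behaviour does not hinge on
any individual coefficient.

Uncertainty propagation (`propagate_storage_uncertainty()`) draws sand,
organic carbon and gravel from truncated normals fitted to 95%
confidence intervals ($\sigma = \mathrm{CI~width}/3.92$), with clay
co-varying as $100 - \mathrm{sand} - \mathrm{silt}$ (silt held at its
mean — a deliberate, maximal negative sand–clay dependence, chosen
because only the existence of the covariance, not its magnitude, is
specified in the sources this design follows). Layer variances are also
combined additively for depth-cumulated uncertainty.

# The daily water balance

Each simulated day proceeds as:

1. **Precipitation partition** at a hard 0 °C threshold into rain and
   snowfall; snow follows a degree-day pack
   (melt $= c_m \max(0, T)$, default $c_m = 2$ mm °C⁻¹ day⁻¹). While
   snow covers the ground, the potential soil-surface evaporation is
   consumed by snow sublimation and soil evaporation is off.
2. **Interception** is a Rutter-style canopy bucket with capacity
   0.25 mm per unit LAI; overflow is throughfall and up to the
   wet-canopy potential evaporates from storage. Transpiration demand is
   reduced by the energy already spent on interception
   ($T_p^{eff} = \max(0, T_p - E_i)$), so the reported $T_p$ is net of
   wet-canopy evaporation and $T_a \le T_p$ holds daily.
3. **Potential fluxes** come from a two-source Shuttleworth–Wallace
   combination: available energy (FAO-style net radiation from global
   radiation, temperature and humidity, with a simple geometric
   slope/aspect factor) is split between canopy and soil by
   $e^{-0.6\,\mathrm{LAI}}$, and the two Penman–Monteith expressions are
   coupled through the standard $C_c$/$C_s$ coefficients. Canopy surface
   resistance is $1/(g_{max}\,\mathrm{LAI}\,f_R\,f_{VPD}\,DL/24)$ with
   the half-saturation reductions $f_R = R/(R+r_5)$ and
   $f_{VPD} = 2^{-VPD/c_{vpd}}$ — each equals 0.5 exactly at its
   reference point — and a daylength factor because stomata are closed
   at night. Aerodynamic resistances use a simplified log-profile
   parameterization from tree height, LAI and wind; this is the least
   constrained part of the model and is documented as such.
4. **Root supply and transpiration.** Each layer's conductance is the
   series combination of a plant-root part
   ($\mathrm{mxkpl}/(1-f_{xylem}) \cdot rf_i$) and a rhizosphere part
   proportional to $K(\psi_i)$; layers act in parallel below a lumped
   xylem conductance ($\mathrm{mxkpl}/f_{xylem}$). The supply rate is
   $S_{max} = g_{tot}\,(\psi_{eff} - \psi_{crit})$ with layers at or
   below $\psi_{crit}$ excluded. Daily demand follows a half-sine over
   the daylength; actual transpiration is the closed-form integral of
   the rate capped at the supply, distributed over layers by supply
   weights. The rhizosphere coefficient (default $10^7$ per MPa, see
   `plant_params()`) is set so that soil-to-root transport only fails
   when $K(\psi)$ itself collapses: with the default, simulated
   drought-summer topsoils dry to pF ≈ 4 before uptake ceases, the
   behaviour reported for drought-gradient forest sites in the field.
5. **Soil evaporation** is the potential soil flux reduced by a surface
   resistance $r_{ss} = \mathrm{rssa}\,\theta_{fc}/\theta_{top}$ that
   equals `rssa` at field capacity and grows as the topsoil dries.
6. **Infiltration** of throughfall plus melt is distributed over the top
   `ilayer` computational layers with cumulative fraction
   $(d/D)^{infexp}$ — `infexp = 0` sends everything to the top layer,
   larger exponents route more water to depth (macropore flow).
7. **Richards redistribution** (below), yielding drainage, surface
   runoff, per-layer uptake and the end-of-day state.

Root distributions follow the beta depth model: the cumulative root
fraction above depth $d$ (m) is $1-\beta^{100d}$ (exponent in cm),
truncated at the maximum rooting depth and renormalized. Phenology uses
a degree-day budburst sum and a trailing-window temperature rule for the
season end (the original season-end method needs inputs this pipeline
does not carry; the surrogate's defaults are a 10 °C threshold over
7 days, not before day 200, falling back to day 280). LAI ramps
linearly over 20 days at both ends of the green season; evergreen
canopies keep 80% of their maximum in winter, deciduous canopies drop
to zero.

# The Richards solver

The column is discretized into layers of at most 10 cm. The solver is a
mass-conservative backward-Euler, modified-Picard scheme on the layer
grid: internodal conductivity is the arithmetic mean of gravel-corrected
layer conductivities, gravity uses head in mm of water
(1 kPa = 101.97 mm), the lower boundary is a unit-gradient flux scaled
by `drain` (1 = free drainage, 0 = sealed), and infiltration excess when
the top layer ponds is handled by switching to a Dirichlet
($\psi_1 = 0$) top with the accepted infiltration defined from the
layer-1 discrete balance — the remainder is surface runoff.

Numerical choices that matter:

* **Wet-end regularization.** The van Genuchten water capacity
  $C = d\theta/d\psi$ vanishes at saturation and a saturated storage
  coefficient takes over discontinuously; a fixed-point iteration then
  limit-cycles across the interface. Above $\psi_E = -0.25$ kPa the
  solver therefore blends $C$ continuously (exponentially, scale 1 kPa)
  from its van Genuchten value at $\psi_E$ down to a small saturated
  storage coefficient ($10^{-4}$ per kPa), integrates $\theta$
  consistently, and lets $K$ rise to $K_s$ on a short (0.1 kPa) scale,
  mirroring the steepness of the true Mualem curve. Saturated-zone
  pressures are carried as state between days; reported matric
  potentials are capped at 0. The public `vg_theta()` / `mualem_k()`
  keep the exact closed forms — the regularization lives only in the
  solver's storage law, and all mass bookkeeping uses that same law, so
  closure is exact.
* **Iteration control.** Picard iterations use adaptive
  under-relaxation, a small capacity floor (pure damping — the converged
  state is set by $\theta(\psi)$, not by $C$), a true nonlinear
  mass-residual convergence test ($10^{-9}$ mm per substep) on top of
  the $\psi$-increment test, and early bail-out on stagnation. Substeps
  halve on non-convergence down to $2^{-10}$ of the step (a hard error
  beyond that); heavy infiltration days start with proportionally finer
  substeps so the first-order time-discretization error stays small.
* **Saturation-excess cascade.** Before each step, per-layer sources are
  capped at the layer's free pore space plus what it can pass downward
  (bounded by interface conductivity and the downstream layers' own
  remaining capacity, recursively); the excess backs up and leaves as
  surface runoff. This keeps extreme parameter combinations (sealed
  lower boundary, reduced porosity) well-posed.

Daily mass-balance closure — precipitation minus evapotranspiration,
runoff and drainage minus the change in soil, snow and canopy storage —
is verified in the test suite to below $10^{-6}$ mm/day on multi-year
runs, and the adaptive solver is checked against a 100×-finer
fixed-substep reference on a one-year toy column (agreement well within
0.1 mm cumulative drainage).

# Calibration by Monte-Carlo filtering

Calibration follows the GLUE / regional-sensitivity-analysis pattern:

* `sample_parameters()` draws uniform, independent vectors from the
  prior table (`default_parameter_specs()`): literature ranges for plant
  and flow parameters (e.g. `glmax` 0.002–0.018 m/s deciduous,
  0.007–0.013 coniferous; `psicr` −4.2 to −0.9 MPa), and ±30%
  multiplicative factors around the pedotransfer prediction for the
  soil-hydraulic parameters ($\alpha$, $n$, $K_s$, $\theta_s$).
* Each run is scored against the sensor record with Nash–Sutcliffe and
  Kling–Gupta (2009) efficiencies per sensor depth, combined as the
  Euclidean distance to the optimum over depths:
  $\mathrm{cof} = \sqrt{\sum_i (1-\mathrm{NSE}_i)^2 +
  (1-\mathrm{KGE}_i)^2}$ (a per-depth-count normalization is available
  behind a flag). Metrics are computed on kPa. Only days whose
  *observation* lies inside the valid sensor range are scored, and the
  *simulation* is clipped to that range first, so states the sensor
  could not have seen are not penalized.
* The `k` lowest-cof runs (default 30 of 5000) are behavioural; ties
  break by run index. Parameter sensitivity is the two-sample
  Kolmogorov–Smirnov distance $D_{max}$ between behavioural and
  non-behavioural marginals (sensitive when $D_{max} > 0.2$; multi-site
  aggregation takes the maximum over site groups, and multi-site
  objectives weight sites equally). Posterior parameter sets are
  per-group medians of the behavioural runs. A parameter vector whose
  simulation fails to converge is scored infinitely bad and can never be
  behavioural.
* `temporal_split()` scores calibration and validation year sets
  independently with the same simulation.

# The synthetic-site generator

`gen_meteo()` produces a sinusoidal annual temperature cycle with an
AR(1) anomaly, Bernoulli wet days with gamma amounts scaled to the
annual normal, clear-sky radiation damped on wet days, humidity tied to
temperature and wetness (so VPD ≥ 0 by construction), and log-normal
wind. The default climate (8 °C mean, 900 mm) sits mid-gradient between
dry inner-alpine and wet pre-alpine forest climates; drought sites are
emulated by scaling precipitation (the recovery experiment uses 0.6,
i.e. ≈540 mm, the dry end of the 650–1370 mm gradient the design
targets). `gen_profile()` jitters three soil templates (deep loam,
shallow stony, sandy) into valid horizon tables.

`gen_observations()` turns a truth simulation into virtual sensor
records: noise is applied on the pF (log) scale (default sd 0.1 pF), so
absolute error grows with dryness as it does for real dielectric matric
potential probes; values outside −9 to −1000 kPa are censored to `NA`
with a censoring flag; and an optional installation artefact makes the
first year wetter by up to 0.3 pF, decaying linearly — mimicking the
root damage around freshly installed sensors.

What the generator does **not** emulate: spatial covariance between
sites, radiation/temperature coupling beyond wet-day cloudiness,
snow-drift or lateral water redistribution, organic forest-floor layers,
and species-specific phenology beyond the deciduous/coniferous split.
Passing the recovery tests therefore demonstrates that the estimation
machinery is self-consistent under the stated noise and censoring model
— not that any particular field data set would be fit equally well.

`recovery_experiment()` chains the full loop: truth parameters (typical
calibrated deciduous values — `psicr` −1.4 MPa, rooting depth 1.6 m,
`betaroot` 0.98) → truth simulation → noisy censored sensors →
Monte-Carlo-filtering calibration → posterior vs truth, $D_{max}$
table, and a temporal calibration/validation split. The validation
design used by the test suite runs 500 samples with 10 behavioural runs
on a 3-year site across 10 seeds, and requires the posterior medians of
the critical stomatal and root parameters to beat the prior midpoint in
at least 8 of 10 seeds; these sizes are the package's own validation
choices and are also what `scripts/acceptance.R` recomputes.

# Drought indices

For a simulation and its column:

* `ta_tp_ratio()` — $\sum T_a / \sum T_p$ per month or year, plus the
  minimum daily ratio per period (undefined periods are flagged `NA`,
  not propagated).
* `transpiration_deficit()` — $\sum (T_p - T_a)$ in mm.
* `adef()` — AWC from the surface to the maximum rooting depth minus
  the current plant-available storage, clamped to $[0, \mathrm{AWC}]$;
  ADEF plus current storage equals AWC identically.
* `relawat()` — current plant-available storage of *rooted* layers over
  their AWC (the rooted-layer normalization is this package's contract;
  1 at field capacity, 0 at wilting).
* `psi_rootzone()` — thickness-weighted mean $\psi$ over the potential
  rooting zone (root-fraction weighting behind a flag).
* `annual_budget()` — annual flux sums per tree type with the exact
  identities $T_d = T_p - T_a$, $E = E_s + E_{sn} + E_i$,
  $\mathrm{ET}_a = T_a + E$, and the mean transpiration reduction
  $\overline{T_d/T_p}$ across tree types per year.

# Known limitations

* The aerodynamic-resistance parameterization is deliberately simple;
  absolute potential-flux magnitudes are plausible but not
  site-calibrated, which is one reason the calibration samples the
  conductance parameters.
* The shipped pedotransfer coefficients are synthetic surrogates (see
  above); analyses that depend on absolute AWC values for real soils
  should substitute locally validated tables.
* One-dimensional columns only: no downslope lateral inflow, so
  water availability on steep convergent terrain is underestimated.
* Daily forcing with a sub-daily half-sine closure for transpiration;
  no energy balance beyond the degree-day snow pack.
* The wet-end regularization trades a ≤0.25 kPa band of the retention
  curve near saturation for solver robustness; matric potential
  dynamics in the sensors' valid range (≤ −9 kPa) are unaffected.
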