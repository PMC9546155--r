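# Daily one-dimensional forest water balance: precipitation partitioning,
# snow, interception, supply-limited transpiration, soil evaporation,
# macropore infiltration and Richards-equation soil water redistribution.

#' Plant (canopy and hydraulic) parameters
#'
#' @param glmax Maximum leaf vapour conductance with fully open stomata
#'   (m/s).
#' @param mxkpl Maximum internal plant conductivity for water flow
#'   (mm/day/MPa).
#' @param psicr Critical leaf water potential at which stomata close
#'   fully (MPa, < 0).
#' @param r5 Shortwave radiation at which leaf conductance is halved
#'   (W/m2).
#' @param cvpd Vapour pressure deficit at which leaf conductance is
#'   halved (kPa).
#' @param fxylem Fraction of plant resistance located in the aboveground
#'   xylem (0-1); the rest sits in the roots.
#' @param cap_lai Canopy interception storage capacity per unit LAI (mm).
#' @param rhiz_c Rhizosphere conductance coefficient (1/MPa): the
#'   soil-to-root conductance of a layer is `rhiz_c * K(psi) * rootfrac`.
#'   The default reflects single-root geometry (dense fine-root systems):
#'   the rhizosphere only limits uptake once the unsaturated conductivity
#'   itself collapses, i.e. near the wilting point.
#' @return Named list of class `plant_params`.
#' @export
plant_params <- function(glmax = 0.0053, mxkpl = 8, psicr = -2, r5 = 100,
                         cvpd = 2, fxylem = 0.5, cap_lai = 0.25,
                         rhiz_c = 1e7) {
  if (glmax <= 0 || mxkpl <= 0 || r5 <= 0 || cvpd <= 0)
    stop("glmax, mxkpl, r5 and cvpd must be > 0")
  if (psicr >= 0) stop("psicr must be < 0 (MPa)")
  if (fxylem < 0 || fxylem > 1) stop("fxylem must be within [0, 1]")
  structure(list(glmax = glmax, mxkpl = mxkpl, psicr = psicr, r5 = r5,
                 cvpd = cvpd, fxylem = fxylem, cap_lai = cap_lai,
                 rhiz_c = rhiz_c), class = "plant_params")
}

#' Soil water flow and surface parameters
#'
#' @param drain Lower boundary factor in `[0, 1]`; 1 is free drainage
#'   (unit-gradient flux `K(psi_N)`), 0 a no-flux boundary.
#' @param ilayer Deepest computational layer (1-based) receiving direct
#'   (macropore-assisted) infiltration.
#' @param infexp Infiltration shape exponent (>= 0); 0 sends all water to
#'   the top layer, larger values shift it to depth within `ilayer`.
#' @param rssa Soil evaporation resistance at field capacity (s/m).
#' @param r_ref Reference aerodynamic resistance for soil evaporation
#'   (s/m).
#' @param snow_melt_coef Degree-day snow melt coefficient (mm/degC/day).
#' @param rain_snow_temp Threshold temperature separating rain from snow
#'   (degC).
#' @return Named list of class `flow_params`.
#' @export
flow_params <- function(drain = 1, ilayer = 1, infexp = 0, rssa = 800,
                        r_ref = 150, snow_melt_coef = 2,
                        rain_snow_temp = 0) {
  if (drain < 0 || drain > 1) stop("drain must be within [0, 1]")
  if (ilayer < 1) stop("ilayer must be >= 1")
  if (infexp < 0) stop("infexp must be >= 0")
  if (rssa <= 0) stop("rssa must be > 0")
  structure(list(drain = drain, ilayer = as.integer(ilayer),
                 infexp = infexp, rssa = rssa, r_ref = r_ref,
                 snow_melt_coef = snow_melt_coef,
                 rain_snow_temp = rain_snow_temp), class = "flow_params")
}

#' Discretize a soil profile into a computational column
#'
#' Horizons are split into computational layers of at most `dz_max`
#' thickness; each layer carries its horizon's hydraulic parameters and
#' gravel fraction, plus a root fraction from the beta depth model.
#'
#' @param profile Horizon table (see [validate_profile()]).
#' @param mvg List of [mvg_params()] per horizon (e.g. [apply_ptf()]).
#' @param betaroot,maxrootdepth Root distribution parameters, see
#'   [root_fractions()].
#' @param dz_max Maximum computational layer thickness (m).
#' @return Object of class `soil_column`: list with `layers` (data.frame),
#'   `matrix` (numeric matrix for the compiled solver), `bounds` (m).
#' @export
soil_column <- function(profile, mvg, betaroot = 0.95, maxrootdepth = 1,
                        dz_max = 0.1) {
  validate_profile(profile)
  if (length(mvg) != nrow(profile))
    stop("need one mvg_params per horizon")
  tops <- c(); bots <- c(); hidx <- c()
  for (i in seq_len(nrow(profile))) {
    th <- profile$bottom_m[i] - profile$top_m[i]
    nsub <- max(1L, ceiling(th / dz_max - 1e-9))
    edges <- seq(profile$top_m[i], profile$bottom_m[i], length.out = nsub + 1)
    tops <- c(tops, edges[-length(edges)])
    bots <- c(bots, edges[-1])
    hidx <- c(hidx, rep(i, nsub))
  }
  pars <- do.call(rbind, lapply(mvg[hidx], function(p) {
    p <- .as_mvg(p)
    c(p$theta_r, p$theta_s, p$alpha, p$n, p$ksat, p$tau)
  }))
  layers <- data.frame(top_m = tops, bottom_m = bots,
                       dz_mm = (bots - tops) * 1000,
                       theta_r = pars[, 1], theta_s = pars[, 2],
                       alpha = pars[, 3], n = pars[, 4], ksat = pars[, 5],
                       tau = pars[, 6], gravel = profile$gravel_frac[hidx])
  bounds <- c(tops[1], bots)
  rf <- root_fractions(betaroot, maxrootdepth, bounds)
  layers$rootfrac <- rf
  m <- as.matrix(layers[, c("dz_mm", "theta_r", "theta_s", "alpha", "n",
                            "ksat", "tau", "gravel")])
  dimnames(m) <- NULL
  structure(list(layers = layers, matrix = m, bounds = bounds,
                 betaroot = betaroot, maxrootdepth = maxrootdepth),
            class = "soil_column")
}

#' Split precipitation into rain and snowfall at a threshold temperature
#'
#' @param precip Daily precipitation (mm, >= 0).
#' @param tmean Daily mean temperature (degC).
#' @param rain_snow_temp Threshold (degC); below it all precipitation is
#'   snow, at or above it all rain.
#' @return List with `rain` and `snowfall` (vectors, mm).
#' @export
partition_precip <- function(precip, tmean, rain_snow_temp = 0) {
  if (any(precip < 0)) stop("precip must be >= 0")
  snow <- ifelse(tmean < rain_snow_temp, precip, 0)
  list(rain = precip - snow, snowfall = snow)
}

#' One day of degree-day snowpack dynamics
#'
#' Melt is `min(swe + snowfall, melt_coef * max(0, tmean))`; snow
#' evaporation takes up to `esn_potential` from the remaining pack.
#'
#' @param swe Snow water equivalent at the start of the day (mm).
#' @param snowfall Snowfall during the day (mm).
#' @param tmean Daily mean temperature (degC).
#' @param melt_coef Degree-day melt coefficient (mm/degC/day).
#' @param esn_potential Potential snow evaporation (mm/day).
#' @return List with `swe` (end of day), `melt`, `esn` (mm).
#' @export
snow_step <- function(swe, snowfall, tmean, melt_coef = 2,
                      esn_potential = 0) {
  stopifnot(swe >= 0, snowfall >= 0)
  pack <- swe + snowfall
  melt <- min(pack, melt_coef * max(0, tmean))
  pack <- pack - melt
  esn <- min(pack, max(0, esn_potential))
  list(swe = pack - esn, melt = melt, esn = esn)
}

#' One day of Rutter-style canopy interception
#'
#' The canopy bucket has capacity `cap_lai * lai`; rain fills it first,
#' overflow becomes throughfall, and up to `ei_potential` evaporates from
#' storage.
#'
#' @param rain Rainfall (mm).
#' @param lai Leaf area index (m2/m2).
#' @param ei_potential Potential wet-canopy evaporation (mm/day).
#' @param storage Canopy storage at the start of the day (mm).
#' @param cap_lai Storage capacity per unit LAI (mm).
#' @return List with `throughfall`, `ei`, `storage` (end of day, mm).
#' @export
interception_step <- function(rain, lai, ei_potential, storage = 0,
                              cap_lai = 0.25) {
  stopifnot(rain >= 0, lai >= 0, storage >= 0)
  cap <- cap_lai * lai
  spill <- max(0, storage - cap)   # canopy shrank below current load
  storage <- storage - spill
  fill <- min(rain, cap - storage)
  storage <- storage + fill
  throughfall <- rain - fill + spill
  ei <- min(storage, max(0, ei_potential))
  storage <- storage - ei
  list(throughfall = throughfall, ei = ei, storage = storage)
}

#' Maximum root water supply rate on the soil-to-leaf pathway
#'
#' Per-layer root and rhizosphere conductances act in series; layers act
#' in parallel and the xylem share `fxylem` of the plant resistance sits
#' above the root junction. Layers at or below the critical potential
#' contribute nothing.
#'
#' @param psi_layers Matric potential per layer (kPa).
#' @param column A [soil_column()].
#' @param plant A [plant_params()].
#' @return List with `smax` (mm/day) and per-layer uptake `weights`.
#' @export
supply_rate <- function(psi_layers, column, plant) {
  stopifnot(length(psi_layers) == nrow(column$layers))
  supply_rate_cpp(as.numeric(psi_layers), column$matrix,
                  column$layers$rootfrac, plant$mxkpl, plant$psicr,
                  plant$fxylem, plant$rhiz_c)
}

#' Supply-limited actual transpiration over a half-sine demand course
#'
#' The daily demand `Tp` is spread over the daylength as a half-sine; the
#' realized rate is capped at the supply rate, and the integral of the
#' capped rate is the actual transpiration.
#'
#' @param tp Potential transpiration (mm/day).
#' @param s_max Supply rate (mm/day), see [supply_rate()].
#' @param daylength Daylength (hours).
#' @param weights Optional per-layer uptake weights; if given, the
#'   per-layer root water uptake is returned too.
#' @return List with `ta` (mm/day) and, if weights are given, `rwu`.
#' @export
actual_transpiration <- function(tp, s_max, daylength, weights = NULL) {
  ta <- half_sine_ta_cpp(tp, s_max, daylength)
  out <- list(ta = ta)
  if (!is.null(weights)) out$rwu <- ta * weights
  out
}

#' Soil evaporation limited by topsoil dryness
#'
#' `Es = Ep_soil * r_ref / (r_ref + rss)` with
#' `rss = rssa * theta_fc / theta_top`: the surface resistance equals
#' `rssa` at field capacity and grows as the topsoil dries.
#'
#' @param ep_soil Potential soil evaporation (mm/day).
#' @param theta_top Topsoil volumetric water content.
#' @param theta_fc Topsoil water content at field capacity (-6.3 kPa).
#' @param rssa Soil surface resistance at field capacity (s/m).
#' @param r_ref Reference aerodynamic resistance (s/m).
#' @return Evaporation (mm/day), `<= ep_soil`.
#' @export
soil_evaporation <- function(ep_soil, theta_top, theta_fc, rssa = 800,
                             r_ref = 150) {
  stopifnot(ep_soil >= 0)
  if (ep_soil == 0 || theta_top <= 0) return(0)
  rss <- rssa * (theta_fc / theta_top)
  ep_soil * r_ref / (r_ref + rss)
}

#' Distribute infiltrating water over the top layers (macropore flow)
#'
#' The cumulative fraction reaching depth d within the top `ilayer`
#' layers is `(d / D)^infexp` with D the bottom of layer `ilayer`;
#' `infexp = 0` sends everything to the top layer, larger exponents shift
#' water to depth.
#'
#' @param water_in Infiltrating water (mm, >= 0).
#' @param column A [soil_column()].
#' @param ilayer Deepest layer receiving direct infiltration (1-based).
#' @param infexp Shape exponent (>= 0).
#' @return Per-layer source vector (mm) summing to `water_in`.
#' @export
infiltrate <- function(water_in, column, ilayer = 1, infexp = 0) {
  stopifnot(water_in >= 0)
  n <- nrow(column$layers)
  ilayer <- min(max(1L, as.integer(ilayer)), n)
  frac <- .infil_fractions(column, ilayer, infexp)
  water_in * frac
}

.infil_fractions <- function(column, ilayer, infexp) {
  n <- nrow(column$layers)
  frac <- numeric(n)
  D <- column$layers$bottom_m[ilayer]
  bnd <- pmin(column$bounds, D) / D
  cum <- if (infexp == 0) as.numeric(bnd > 0) else bnd^infexp
  cum[length(cum)] <- max(cum[length(cum)], 1)  # guard rounding
  frac[1:ilayer] <- diff(cum[1:(ilayer + 1)])
  frac / sum(frac)
}

#' One Richards-equation step on the soil column
#'
#' Implicit (backward-Euler, modified-Picard) mass-conservative solve on
#' the layer grid with arithmetic-mean internodal conductivity, a
#' unit-gradient lower boundary scaled by `drain`, and surface runoff
#' when the top layer saturates. Sub-steps are halved adaptively on
#' non-convergence (down to 2^-10 of the step).
#'
#' @param psi Matric potential per layer (kPa, <= 0).
#' @param column A [soil_column()].
#' @param sources Per-layer water sources (mm/day).
#' @param sinks Per-layer extractions (mm/day).
#' @param flow A [flow_params()] (only `drain` is used here).
#' @param dt Step length (days).
#' @param fixed_substeps If > 0, force this many equal sub-steps (used
#'   for refinement studies); 0 means adaptive.
#' @return List with `psi`, `drainage` (mm), `runoff` (mm), `residual`
#'   (mm, mass-balance), `swat` (total soil water, mm).
#' @export
richards_step <- function(psi, column, sources, sinks, flow, dt = 1,
                          fixed_substeps = 0) {
  stopifnot(dt > 0, length(psi) == nrow(column$layers))
  richards_step_cpp(as.numeric(psi), column$matrix, as.numeric(sources),
                    as.numeric(sinks), flow$drain, dt,
                    as.integer(fixed_substeps))
}

#' Total soil water of a column state (mm)
#'
#' @param psi Matric potential per layer (kPa).
#' @param column A [soil_column()].
#' @export
soil_water_mm <- function(psi, column) {
  l <- column$layers
  th <- vapply(seq_len(nrow(l)), function(i)
    vg_theta_cpp(psi[i], l$theta_r[i], l$theta_s[i], l$alpha[i], l$n[i]),
    numeric(1))
  sum(th * l$dz_mm * (1 - l$gravel))
}

#' Run the daily water-balance simulation
#'
#' Chains phenology, the Shuttleworth-Wallace potential-flux partition,
#' degree-day snow, Rutter interception, supply-limited transpiration
#' with per-layer root uptake, moisture-limited soil evaporation,
#' macropore infiltration and the Richards soil water solver over a
#' multi-year daily forcing series. Deterministic (no RNG).
#'
#' @param meteo Daily meteorology, see [prepare_meteo()] for the format;
#'   at least one full calendar year.
#' @param site List with `lat`, `elevation`, `slope`, `aspect`,
#'   `tree_type` (`"deciduous"` or `"coniferous"`), `height` (m),
#'   `maxlai`.
#' @param plant A [plant_params()].
#' @param flow A [flow_params()].
#' @param column A [soil_column()].
#' @param phenology A [phenology_params()].
#' @param psi_init Initial matric potential (kPa), recycled over layers.
#' @param spinup_years Number of leading calendar years flagged as
#'   spin-up in the output (excluded from analyses, not from the run).
#' @return Object of class `svat_run`: list with `fluxes` (one row per
#'   day: P, rain, snowfall, F, runoff, drainage, ETa, Ta, Tp, Td, Es,
#'   Esn, Ei, SWAT, swe, intercepted, lai, spinup), matrices `psi` and
#'   `rwu` (days x layers), and the inputs.
#' @export
run_simulation <- function(meteo, site, plant = plant_params(),
                           flow = flow_params(), column, phenology =
                             phenology_params(), psi_init = -6.3,
                           spinup_years = 0) {
  meteo <- prepare_meteo(meteo)
  years <- unique(meteo$year)
  full <- vapply(years, function(y) sum(meteo$year == y) >= 365, logical(1))
  if (!any(full)) stop("meteo must cover at least one full calendar year")
  tree <- match.arg(site$tree_type, c("deciduous", "coniferous"))
  winter_frac <- if (tree == "coniferous") 0.8 else 0

  # daily LAI from per-year phenology
  lai <- numeric(nrow(meteo))
  for (y in years) {
    iy <- which(meteo$year == y)
    tm <- meteo$tmean[iy]
    if (length(iy) >= 365) {
      bb <- budburst_doy(tm, phenology)
      se <- season_end_doy(tm, phenology)
      if (!is.na(bb)) se <- max(se, bb + 2)
      lai[iy] <- lai_course(bb, se, site$maxlai, winter_frac,
                            n_days = length(iy))
    } else {
      lai[iy] <- winter_frac * site$maxlai   # partial year: winter value
    }
  }

  pot <- potential_fluxes(meteo, lai, plant, site)
  pp <- partition_precip(meteo$prec, meteo$tmean, flow$rain_snow_temp)

  nd <- nrow(meteo)
  melt <- esn <- thr <- ei <- swe_v <- int_v <- numeric(nd)
  eps_eff <- numeric(nd)
  swe <- 0; canopy <- 0
  for (d in seq_len(nd)) {
    snow_present <- (swe + pp$snowfall[d]) > 0
    st <- snow_step(swe, pp$snowfall[d], meteo$tmean[d],
                    flow$snow_melt_coef,
                    if (snow_present) pot$ep_soil[d] else 0)
    swe <- st$swe; melt[d] <- st$melt; esn[d] <- st$esn
    eps_eff[d] <- if (snow_present) 0 else pot$ep_soil[d]
    ic <- interception_step(pp$rain[d], lai[d], pot$ep_int[d], canopy,
                            plant$cap_lai)
    canopy <- ic$storage; thr[d] <- ic$throughfall; ei[d] <- ic$ei
    swe_v[d] <- swe; int_v[d] <- canopy
  }
  tp_eff <- pmax(0, pot$tp - ei)

  frac <- .infil_fractions(column, min(flow$ilayer, nrow(column$layers)),
                           flow$infexp)
  infil <- outer(thr + melt, frac)

  psi0 <- rep_len(psi_init, nrow(column$layers))
  sl <- soil_loop_cpp(psi0, column$matrix, column$layers$rootfrac, infil,
                      tp_eff, eps_eff, pot$daylength, plant$mxkpl,
                      plant$psicr, plant$fxylem, plant$rhiz_c, flow$rssa,
                      flow$r_ref, flow$drain)

  eta <- sl$ta + sl$es + esn + ei
  fluxes <- data.frame(
    date = meteo$date, year = meteo$year, doy = meteo$doy,
    P = meteo$prec, rain = pp$rain, snowfall = pp$snowfall,
    F = sl$runoff + sl$drainage, runoff = sl$runoff,
    drainage = sl$drainage, ETa = eta, Ta = sl$ta, Tp = tp_eff,
    Td = tp_eff - sl$ta, Es = sl$es, Esn = esn, Ei = ei,
    SWAT = sl$swat, swe = swe_v, intercepted = int_v, lai = lai,
    residual = sl$residual,
    spinup = meteo$year %in% years[seq_len(min(spinup_years,
                                               length(years)))])
  structure(list(fluxes = fluxes, psi = sl$psi, rwu = sl$rwu,
                 column = column, site = site, plant = plant,
                 flow = flow, phenology = phenology),
            class = "svat_run")
}

#' Daily water-balance closure of a simulation
#'
#' Computes `P - ETa - F - dSWAT - dSWE - dIntercepted` per day; values
#' should be ~0 (the solver closes mass to numerical precision).
#'
#' @param run An object from [run_simulation()].
#' @param psi_init The initial potential used for the run (kPa).
#' @return Numeric vector of daily residuals (mm).
#' @export
mass_balance <- function(run, psi_init = -6.3) {
  f <- run$fluxes
  swat0 <- soil_water_mm(rep_len(psi_init, nrow(run$column$layers)),
                         run$column)
  dswat <- diff(c(swat0, f$SWAT))
  dswe <- diff(c(0, f$swe))
  dint <- diff(c(0, f$intercepted))
  f$P - f$ETa - f$F - dswat - dswe - dint
}
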