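# Synthetic study sites: seasonal meteorology, plausible soil profiles
# and truncated-range virtual matric potential sensors generated from a
# known-truth model run. Everything is reproducible under a seed.

#' Climate specification for the weather generator
#'
#' @param mat Mean annual temperature (degC).
#' @param amplitude Seasonal temperature amplitude (degC, peak minus
#'   mean).
#' @param annual_precip Mean annual precipitation (mm).
#' @param wet_prob Wet-day probability.
#' @param gamma_shape Gamma shape of daily wet-day amounts.
#' @param ar1 Lag-1 autocorrelation of the temperature anomaly.
#' @param anom_sd Standard deviation of the daily temperature anomaly
#'   (degC).
#' @return Named list of class `climate_spec`.
#' @export
climate_spec <- function(mat = 8, amplitude = 9, annual_precip = 900,
                         wet_prob = 0.35, gamma_shape = 0.8, ar1 = 0.7,
                         anom_sd = 2.5) {
  if (wet_prob < 0 || wet_prob > 1) stop("wet_prob must be in [0, 1]")
  if (annual_precip <= 0) stop("annual_precip must be > 0")
  structure(list(mat = mat, amplitude = amplitude,
                 annual_precip = annual_precip, wet_prob = wet_prob,
                 gamma_shape = gamma_shape, ar1 = ar1, anom_sd = anom_sd),
            class = "climate_spec")
}

#' Generate daily meteorology for a synthetic site
#'
#' Sinusoidal annual temperature cycle with an AR(1) anomaly,
#' Bernoulli wet-day occurrence with gamma amounts (scaled so the
#' long-run annual total matches the specification), clear-sky
#' radiation damped on wet days, and humidity tied to temperature and
#' wetness so the vapour pressure deficit is always non-negative.
#'
#' @param spec A [climate_spec()].
#' @param n_years Number of calendar years (starting 2013-01-01).
#' @param seed Integer RNG seed.
#' @param lat Latitude (degrees) for the radiation curve.
#' @param elevation Elevation (m).
#' @param precip_scale Multiplier on all precipitation (drought
#'   scenarios).
#' @return Daily meteorology data.frame (see [prepare_meteo()]).
#' @export
gen_meteo <- function(spec = climate_spec(), n_years = 3, seed = 1L,
                      lat = 47, elevation = 600, precip_scale = 1) {
  if (n_years < 1) stop("n_years must be >= 1")
  set.seed(seed)
  dates <- seq(as.Date("2013-01-01"),
               as.Date(sprintf("%d-12-31", 2012 + n_years)), by = "day")
  nd <- length(dates)
  doy <- as.integer(format(dates, "%j"))

  anom <- numeric(nd)
  innov <- rnorm(nd, 0, spec$anom_sd * sqrt(1 - spec$ar1^2))
  for (d in 2:nd) anom[d] <- spec$ar1 * anom[d - 1] + innov[d]
  tmean <- spec$mat + spec$amplitude * cos(2 * pi * (doy - 200) / 365.25) +
    anom
  drange <- pmax(2, 8 + rnorm(nd, 0, 1.5))
  tmin <- tmean - drange / 2
  tmax <- tmean + drange / 2

  wet <- runif(nd) < spec$wet_prob
  mean_amt <- spec$annual_precip / (365.25 * spec$wet_prob)
  prec <- numeric(nd)
  prec[wet] <- rgamma(sum(wet), shape = spec$gamma_shape,
                      scale = mean_amt / spec$gamma_shape)
  prec <- prec * precip_scale

  ra <- .ra_extraterrestrial(lat, doy)
  rso <- (0.75 + 2e-5 * elevation) * ra
  cloud <- ifelse(wet, 0.35, 0.72) + rnorm(nd, 0, 0.05)
  globrad <- pmax(0.5, rso * pmin(0.85, pmax(0.15, cloud)))

  rh <- pmin(98, pmax(30, ifelse(wet, 88, 62) + rnorm(nd, 0, 6)))
  vp <- .es_kpa(tmean) * rh / 100
  wind <- pmax(0.3, exp(rnorm(nd, log(2), 0.4)))

  data.frame(date = dates, tmin = tmin, tmean = tmean, tmax = tmax,
             prec = prec, vp = vp, globrad = globrad, wind = wind)
}

#' Generate a plausible layered soil profile
#'
#' Templates mimic shallow stony uplands, deep loams and sandy soils;
#' textures are jittered and renormalized to sum to 100%.
#'
#' @param template One of `"shallow_stony"`, `"deep_loam"`, `"sandy"`.
#' @param seed Integer RNG seed.
#' @return Horizon table passing [validate_profile()].
#' @export
gen_profile <- function(template = c("deep_loam", "shallow_stony",
                                     "sandy"), seed = 1L) {
  template <- match.arg(template)
  set.seed(seed)
  base <- switch(template,
    deep_loam = list(bottoms = c(0.1, 0.3, 0.6, 1.0, 1.5, 1.8),
                     sand = 38, silt = 40, clay = 22, gravel = 0.08,
                     bd = 1.35, corg0 = 3.5),
    shallow_stony = list(bottoms = c(0.1, 0.25, 0.45, 0.6),
                         sand = 48, silt = 34, clay = 18, gravel = 0.45,
                         bd = 1.3, corg0 = 4),
    sandy = list(bottoms = c(0.15, 0.4, 0.8, 1.2, 1.6),
                 sand = 74, silt = 18, clay = 8, gravel = 0.12,
                 bd = 1.5, corg0 = 2))
  nb <- length(base$bottoms)
  sand <- pmin(92, pmax(3, base$sand + rnorm(nb, 0, 4) +
                          seq(0, 6, length.out = nb)))
  clay <- pmin(70, pmax(2, base$clay + rnorm(nb, 0, 2) +
                          seq(0, 3, length.out = nb)))
  silt <- pmax(2, 100 - sand - clay)
  tot <- sand + silt + clay
  sand <- sand / tot * 100; silt <- silt / tot * 100
  clay <- 100 - sand - silt
  gravel <- pmin(0.85, pmax(0, base$gravel +
                              seq(0, 0.15, length.out = nb) +
                              rnorm(nb, 0, 0.03)))
  prof <- data.frame(
    top_m = c(0, base$bottoms[-nb]), bottom_m = base$bottoms,
    sand_pct = sand, silt_pct = silt, clay_pct = clay,
    gravel_frac = gravel,
    bd_gcm3 = pmin(1.8, base$bd + seq(0, 0.25, length.out = nb)),
    corg_pct = pmax(0.1, base$corg0 * exp(-2.5 * c(0, base$bottoms[-nb]))))
  validate_profile(prof)
  prof
}

#' Virtual matric potential sensor specification
#'
#' @param depths Sensor depths (m).
#' @param noise_sd Observation noise standard deviation on the pF
#'   (log10) scale.
#' @param valid_range Valid measurement range (kPa), default
#'   c(-1000, -9).
#' @param install_bias_days Days over which the post-installation wet
#'   bias decays to zero.
#' @param install_bias_pf Initial wet bias magnitude (pF units; applied
#'   toward wetter, i.e. lower pF).
#' @return Named list of class `sensor_spec`.
#' @export
sensor_spec <- function(depths = c(0.2, 0.8), noise_sd = 0.1,
                        valid_range = SENSOR_RANGE,
                        install_bias_days = 0, install_bias_pf = 0.3) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(depths = depths, noise_sd = noise_sd,
                 valid_range = valid_range,
                 install_bias_days = install_bias_days,
                 install_bias_pf = install_bias_pf),
            class = "sensor_spec")
}

#' Generate virtual sensor observations from a truth simulation
#'
#' Truth matric potentials at the sensor layers receive multiplicative
#' noise on the pF (log) scale — sensor error grows with dryness — an
#' optional linearly decaying wet bias after installation, and are then
#' censored to the valid measurement range (`NA` outside it).
#'
#' @param run A truth [run_simulation()] result.
#' @param sensors A [sensor_spec()].
#' @param seed Integer RNG seed.
#' @return Observation table: `date`, `depth_m`, `psi_kpa` (kPa; `NA`
#'   where censored), `censored` (`"low"`, `"high"` or `""`).
#' @export
gen_observations <- function(run, sensors = sensor_spec(), seed = 1L) {
  set.seed(seed)
  col <- run$column
  mid <- (col$layers$top_m + col$layers$bottom_m) / 2
  if (any(sensors$depths > max(col$layers$bottom_m) + 1e-9))
    stop("sensor depth below the soil column")
  out <- list()
  nd <- nrow(run$psi)
  for (dep in sensors$depths) {
    lay <- which.min(abs(mid - dep))
    truth <- pmin(run$psi[, lay], -1e-3)
    pfv <- psi_to_pf(truth) + rnorm(nd, 0, sensors$noise_sd)
    if (sensors$install_bias_days > 0) {
      decay <- pmax(0, 1 - (seq_len(nd) - 1) / sensors$install_bias_days)
      pfv <- pfv - sensors$install_bias_pf * decay   # wetter = lower pF
    }
    psi_obs <- pf_to_psi(pfv)
    cens <- ifelse(psi_obs < sensors$valid_range[1], "low",
                   ifelse(psi_obs > sensors$valid_range[2], "high", ""))
    psi_obs[cens != ""] <- NA_real_
    out[[length(out) + 1]] <- data.frame(
      date = run$fluxes$date, depth_m = dep, psi_kpa = psi_obs,
      censored = cens)
  }
  do.call(rbind, out)
}

#' Default truth parameters of the recovery experiment
#'
#' Values typical of calibrated deciduous forest stands: early stomatal
#' closure around -1.4 MPa, deep rooting, and a slowly declining root
#' density profile.
#'
#' @return Named list of truth values for the calibrated parameters.
#' @export
recovery_truth_defaults <- function() {
  list(psicr = -1.4, maxrootdepth = 1.6, betaroot = 0.98, glmax = 0.011,
       mxkpl = 10, drain = 0.6)
}

#' Known-truth parameter recovery experiment
#'
#' Generates a synthetic site (meteorology, profile), runs the model
#' with known truth parameters, produces noisy censored sensor
#' observations, calibrates against them by Monte-Carlo filtering, and
#' reports truth vs behavioural posterior medians, the `D_max`
#' sensitivity table and the temporal-split calibration/validation
#' efficiencies.
#'
#' @param n_samples Ensemble size.
#' @param k Behavioural set size.
#' @param n_years Simulated years (first year is spin-up).
#' @param seed Integer RNG seed (controls weather, profile, noise and
#'   sampling).
#' @param template Soil profile template, see [gen_profile()].
#' @param truth Truth parameter list, see [recovery_truth_defaults()].
#' @param precip_scale Precipitation multiplier (drought severity).
#' @param specs Prior table; defaults to [default_parameter_specs()].
#' @return List with `truth`, `posterior_median`, `prior_midpoint`,
#'   `sensitivity`, `cal_val` (temporal split of the best run),
#'   `calibration` (the full `mc_calibration` object) and `site` data.
#' @export
recovery_experiment <- function(n_samples = 500, k = 10, n_years = 3,
                                seed = 1L, template = "deep_loam",
                                truth = recovery_truth_defaults(),
                                precip_scale = 0.6, specs = NULL) {
  site <- list(lat = 47, elevation = 600, slope = 0, aspect = 180,
               tree_type = "deciduous", height = 25, maxlai = 4.6)
  meteo <- gen_meteo(climate_spec(), n_years, seed = seed,
                     precip_scale = precip_scale)
  profile <- gen_profile(template, seed = seed + 1000L)
  mvg <- apply_ptf(profile, "wessolek")
  if (is.null(specs)) specs <- default_parameter_specs(site$tree_type)

  truth_row <- as.data.frame(truth)
  cfg <- .apply_sample(truth_row, plant_params(), flow_params(),
                       profile, mvg)
  truth_run <- run_simulation(meteo, site, cfg$plant, cfg$flow,
                              cfg$column, spinup_years = 1)
  obs <- gen_observations(truth_run, sensor_spec(), seed = seed + 2000L)

  cal <- calibrate_site(meteo, site, profile, mvg, obs, specs = specs,
                        n = n_samples, k = k, seed = seed + 3000L,
                        spinup_years = 1)
  post <- cal$posterior
  midpoint <- setNames((specs$low + specs$high) / 2, specs$name)

  # temporal split on the best behavioural run
  best <- cal$samples[cal$best, specs$name, drop = FALSE]
  cfg_b <- .apply_sample(best, plant_params(), flow_params(), profile, mvg)
  run_b <- run_simulation(meteo, site, cfg_b$plant, cfg_b$flow,
                          cfg_b$column, spinup_years = 1)
  yrs <- sort(unique(run_b$fluxes$year[!run_b$fluxes$spinup]))
  cal_val <- if (length(yrs) >= 2)
    temporal_split(run_b, obs, head(yrs, -1), tail(yrs, 1)) else NULL

  list(truth = truth,
       posterior_median = post[, setdiff(names(post), "group")],
       prior_midpoint = midpoint, sensitivity = cal$sensitivity,
       cal_val = cal_val, calibration = cal,
       site = list(site = site, meteo = meteo, profile = profile,
                   obs = obs, truth_run = truth_run))
}
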