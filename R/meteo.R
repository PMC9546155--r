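# Meteorology helpers and the Shuttleworth-Wallace two-source partition of
# potential evaporation fluxes.

# saturation vapour pressure (kPa) and its slope (kPa/K), Magnus form
.es_kpa <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
.delta_kpa <- function(t) 4098 * .es_kpa(t) / (t + 237.3)^2

# psychrometric constant (kPa/K) from elevation (m)
.gamma_kpa <- function(elev) {
  p <- 101.3 * ((293 - 0.0065 * elev) / 293)^5.26
  0.000665 * p
}

#' Astronomical daylength
#'
#' @param lat Latitude in decimal degrees.
#' @param doy Day-of-year (vectorized).
#' @return Daylength in hours.
#' @export
daylength_hours <- function(lat, doy) {
  decl <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  x <- pmin(1, pmax(-1, -tan(lat * pi / 180) * tan(decl)))
  ws <- acos(x)
  24 / pi * ws
}

# extraterrestrial radiation (MJ/m2/day)
.ra_extraterrestrial <- function(lat, doy) {
  phi <- lat * pi / 180
  decl <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  x <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  ws <- acos(x)
  24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
}

# simple geometric slope/aspect factor on incident shortwave; south-facing
# slopes (aspect 180 deg) receive more, north-facing less
.slope_factor <- function(slope_deg, aspect_deg) {
  f <- 1 + 0.4 * sin(slope_deg * pi / 180) * cos((aspect_deg - 180) * pi / 180)
  pmax(0.3, f)
}

#' Validate and complete a daily meteorology table
#'
#' Requires columns `date`, `tmin`, `tmean`, `tmax`, `prec`, `globrad`,
#' `wind`, and either `vp` (vapour pressure, kPa) or `rh` (%). Derives
#' `doy`, `year`, actual vapour pressure `ea` and `vpd` (both kPa).
#'
#' @param meteo data.frame of daily forcing.
#' @return The completed data.frame.
#' @export
prepare_meteo <- function(meteo) {
  need <- c("date", "tmin", "tmean", "tmax", "prec", "globrad", "wind")
  miss <- setdiff(need, names(meteo))
  if (length(miss)) stop("meteo missing columns: ", paste(miss, collapse = ", "))
  if (!("vp" %in% names(meteo)) && !("rh" %in% names(meteo)))
    stop("meteo needs a vapour pressure (vp, kPa) or relative humidity (rh, %) column")
  meteo$date <- as.Date(meteo$date)
  if (any(diff(meteo$date) != 1)) stop("meteo days must be consecutive")
  if (any(meteo$prec < 0)) stop("precipitation must be >= 0")
  if (any(meteo$globrad < 0)) stop("global radiation must be >= 0")
  if (any(meteo$tmin > meteo$tmean + 1e-9 | meteo$tmean > meteo$tmax + 1e-9))
    stop("require tmin <= tmean <= tmax")
  meteo$doy <- as.integer(format(meteo$date, "%j"))
  meteo$year <- as.integer(format(meteo$date, "%Y"))
  es <- .es_kpa(meteo$tmean)
  meteo$ea <- if ("vp" %in% names(meteo)) meteo$vp else es * meteo$rh / 100
  meteo$vpd <- pmax(0, es - meteo$ea)
  meteo
}

#' Radiation reduction factor on leaf conductance
#'
#' `f_R = R / (R + r5)`; equals 0.5 when the shortwave level R equals r5.
#' @param r Shortwave radiation at leaf level (W/m2).
#' @param r5 Radiation at which conductance is halved (W/m2).
#' @export
conductance_f_radiation <- function(r, r5) r / (r + r5)

#' Vapour-pressure-deficit reduction factor on leaf conductance
#'
#' `f_VPD = 2^(-VPD/cvpd)`; equals 0.5 when VPD equals cvpd.
#' @param vpd Vapour pressure deficit (kPa).
#' @param cvpd VPD at which conductance is halved (kPa).
#' @export
conductance_f_vpd <- function(vpd, cvpd) 2^(-vpd / cvpd)

#' Two-source (Shuttleworth-Wallace) potential evaporation fluxes
#'
#' Partitions available energy between canopy and soil and combines the
#' two Penman-Monteith expressions with the Shuttleworth-Wallace coupling
#' coefficients. Canopy surface resistance is
#' `1 / (glmax * LAI * f_R * f_VPD)`; the potential soil flux uses zero
#' soil surface resistance (moisture limitation is applied later by
#' [soil_evaporation()]); the wet-canopy (interception) potential uses
#' zero canopy resistance. Aerodynamic resistances follow a simplified
#' log-profile parameterization from tree height, LAI and wind speed.
#'
#' @param meteo Prepared meteorology (see [prepare_meteo()]), vectorized.
#' @param lai Daily leaf area index vector (same length).
#' @param plant A [plant_params()] object.
#' @param site Site list with `lat`, `elevation`, `slope`, `aspect`,
#'   `height` (tree height, m).
#' @return data.frame with `tp` (potential transpiration), `ep_soil`
#'   (potential soil evaporation) and `ep_int` (wet-canopy potential),
#'   all mm/day.
#' @export
potential_fluxes <- function(meteo, lai, plant, site) {
  stopifnot(length(lai) == nrow(meteo))
  h <- max(site$height, 2)
  dl <- daylength_hours(site$lat, meteo$doy)
  rg_mj <- meteo$globrad * .slope_factor(site$slope %||% 0,
                                         site$aspect %||% 180)
  rg_w <- rg_mj * 1e6 / 86400
  # FAO-style net radiation
  ra_mj <- .ra_extraterrestrial(site$lat, meteo$doy)
  rso <- pmax((0.75 + 2e-5 * (site$elevation %||% 500)) * ra_mj, 0.1)
  ratio <- pmin(1, pmax(0.3, rg_mj / rso))
  tk4 <- 4.903e-9 * ((meteo$tmax + 273.16)^4 + (meteo$tmin + 273.16)^4) / 2
  rnl <- tk4 * (0.34 - 0.14 * sqrt(pmax(meteo$ea, 0.01))) *
    (1.35 * ratio - 0.35)
  rn_w <- pmax(0, ((1 - 0.12) * rg_mj - rnl) * 1e6 / 86400)

  A <- rn_w
  As <- A * exp(-0.6 * lai)
  delta <- .delta_kpa(meteo$tmean) * 1000  # Pa/K
  gam <- .gamma_kpa(site$elevation %||% 500) * 1000
  D <- meteo$vpd * 1000                    # Pa
  rho_cp <- 1.2 * 1013
  u <- pmax(meteo$wind, 0.5)

  d0 <- 0.67 * h; z0 <- 0.123 * h; zm <- h + 2
  raa <- log((zm - d0) / z0)^2 / (0.41^2 * u)
  rac <- pmin(5000, 50 / pmax(lai, 0.01))
  ras <- 60 * exp(0.25 * lai)

  rday <- rg_w * 24 / pmax(dl, 1)          # daytime mean shortwave
  fr <- conductance_f_radiation(rday, plant$r5)
  fv <- conductance_f_vpd(meteo$vpd, plant$cvpd)
  # daily-mean canopy conductance: stomata operate only during daylight
  gc <- plant$glmax * lai * fr * fv * dl / 24  # m/s
  rsc <- ifelse(gc > 1e-9, 1 / gc, 1e9)

  pm <- function(A_, As_, ra_, rb_, rs_) {
    (delta * A_ + (rho_cp * D - delta * rb_ * As_) / (ra_ + rb_)) /
      (delta + gam * (1 + rs_ / (ra_ + rb_)))
  }
  # each source's PM subtracts the energy available to the *other* source
  pmc <- pm(A, As, raa, rac, rsc)          # canopy source (W/m2)
  pms <- pm(A, A - As, raa, ras, 0)        # soil source, potential (rss = 0)
  Ra_ <- (delta + gam) * raa
  Rc_ <- (delta + gam) * rac + gam * rsc
  Rs_ <- (delta + gam) * ras
  cc <- 1 / (1 + Rc_ * Ra_ / (Rs_ * (Rc_ + Ra_)))
  cs <- 1 / (1 + Rs_ * Ra_ / (Rc_ * (Rs_ + Ra_)))
  to_mm <- 86400 / 2.45e6
  tp <- pmax(0, cc * pmc * to_mm)
  ep_soil <- pmax(0, cs * pms * to_mm)
  # wet canopy: single-source PM with zero canopy resistance
  ep_int <- pmax(0, (delta * A + rho_cp * D / raa) / (delta + gam) * to_mm)
  tp[lai <= 0] <- 0
  data.frame(tp = tp, ep_soil = ep_soil, ep_int = ep_int, daylength = dl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
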