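# Physiological drought indices and water-budget aggregation from
# simulation output.

.period_key <- function(dates, period = c("month", "year")) {
  period <- match.arg(period)
  if (period == "year") format(as.Date(dates), "%Y")
  else format(as.Date(dates), "%Y-%m")
}

#' Ratio of actual to potential transpiration per period
#'
#' `sum(Ta) / sum(Tp)` per calendar month or year, plus the minimum
#' daily ratio within the period (days with `Tp > 0`).
#'
#' @param fluxes Daily flux table from [run_simulation()] (columns
#'   `date`, `Ta`, `Tp`).
#' @param period `"month"` or `"year"`.
#' @return data.frame with `period`, `ta_tp` (NA-flagged where
#'   `sum(Tp) = 0`), `ta_tp_min_daily`.
#' @export
ta_tp_ratio <- function(fluxes, period = "month") {
  key <- .period_key(fluxes$date, period)
  out <- lapply(split(fluxes, key), function(f) {
    stp <- sum(f$Tp)
    daily <- f$Ta[f$Tp > 0] / f$Tp[f$Tp > 0]
    data.frame(ta_tp = if (stp > 0) sum(f$Ta) / stp else NA_real_,
               ta_tp_min_daily = if (length(daily)) min(daily) else NA_real_)
  })
  data.frame(period = names(out), do.call(rbind, out), row.names = NULL)
}

#' Transpiration deficit per period
#'
#' `sum(Tp - Ta)` (mm) per calendar month or year.
#'
#' @inheritParams ta_tp_ratio
#' @return data.frame with `period` and `td_mm`.
#' @export
transpiration_deficit <- function(fluxes, period = "year") {
  key <- .period_key(fluxes$date, period)
  td <- vapply(split(fluxes$Tp - fluxes$Ta, key), sum, numeric(1))
  data.frame(period = names(td), td_mm = pmax(0, unname(td)),
             row.names = NULL)
}

# plant-available storage (mm) per layer of a column state, and its AWC
.pa_storage <- function(psi, column, layer_sel = NULL) {
  l <- column$layers
  if (is.null(layer_sel)) layer_sel <- seq_len(nrow(l))
  cur <- awcl <- numeric(length(layer_sel))
  for (k in seq_along(layer_sel)) {
    i <- layer_sel[k]
    th <- vg_theta_cpp(c(psi[i], PSI_WILTING, PSI_FIELD_CAPACITY),
                       l$theta_r[i], l$theta_s[i], l$alpha[i], l$n[i])
    fe <- 1 - l$gravel[i]
    cur[k] <- max(0, th[1] - th[2]) * l$dz_mm[i] * fe
    awcl[k] <- (th[3] - th[2]) * l$dz_mm[i] * fe
  }
  list(current = cur, awc = awcl)
}

#' Deficit of plant-available water in the root zone (ADEF)
#'
#' AWC from the mineral soil surface to the maximum rooting depth minus
#' the current plant-available storage, clamped to `[0, AWC]`.
#'
#' @param psi Matric potential per layer (kPa) for one day.
#' @param column A [soil_column()].
#' @param maxrootdepth Maximum rooting depth (m); defaults to the
#'   column's.
#' @return Deficit in mm.
#' @export
adef <- function(psi, column, maxrootdepth = column$maxrootdepth) {
  if (maxrootdepth > max(column$layers$bottom_m) + 1e-9)
    stop("rooting depth exceeds the soil column")
  sel <- which(column$layers$top_m < maxrootdepth - 1e-12)
  st <- .pa_storage(psi, column, sel)
  # partial inclusion of the layer straddling the rooting depth
  fracs <- pmin(1, (maxrootdepth - column$layers$top_m[sel]) /
                  (column$layers$bottom_m[sel] - column$layers$top_m[sel]))
  awc <- sum(st$awc * fracs)
  min(max(awc - sum(st$current * fracs), 0), awc)
}

#' Relative plant-available soil water in rooted layers (RELAWAT)
#'
#' Current plant-available storage of layers with roots divided by
#' their AWC; 1 at field capacity, 0 at the wilting point.
#'
#' @param psi Matric potential per layer (kPa) for one day.
#' @param column A [soil_column()].
#' @return Ratio in `[0, 1]`.
#' @export
relawat <- function(psi, column) {
  sel <- which(column$layers$rootfrac > 0)
  if (!length(sel)) stop("no layer has roots")
  st <- .pa_storage(psi, column, sel)
  min(1, max(0, sum(st$current) / sum(st$awc)))
}

#' Mean matric potential in the (potential) rooting zone
#'
#' Thickness-weighted mean over layers above the rooting depth;
#' root-fraction weighting is available behind a flag.
#'
#' @param psi Matric potential per layer (kPa).
#' @param column A [soil_column()].
#' @param maxrootdepth Rooting depth (m), defaults to the column's.
#' @param weighting `"thickness"` or `"roots"`.
#' @return Mean potential (kPa).
#' @export
psi_rootzone <- function(psi, column, maxrootdepth = column$maxrootdepth,
                         weighting = c("thickness", "roots")) {
  weighting <- match.arg(weighting)
  if (maxrootdepth <= 0) stop("rooting depth must be > 0")
  sel <- which(column$layers$top_m < maxrootdepth - 1e-12)
  w <- if (weighting == "thickness") {
    pmin(column$layers$bottom_m[sel], maxrootdepth) -
      column$layers$top_m[sel]
  } else column$layers$rootfrac[sel]
  sum(psi[sel] * w) / sum(w)
}

#' pF value of a matric potential
#'
#' `log10` of the potential's magnitude expressed in hPa
#' (1 kPa = 10 hPa): -10 kPa is pF 2, -1000 kPa is pF 4.
#'
#' @param psi Matric potential (kPa, < 0).
#' @return pF (dimensionless); vectorized.
#' @export
psi_to_pf <- function(psi) {
  if (any(psi >= 0)) stop("pF undefined for psi >= 0")
  log10(abs(psi) * 10)
}

#' Inverse of [psi_to_pf()]: matric potential from a pF value
#' @param pf_val pF value.
#' @return Matric potential (kPa, < 0).
#' @export
pf_to_psi <- function(pf_val) -(10^pf_val) / 10

#' Annual water budget per tree type
#'
#' Annual sums of all water-balance fluxes per calendar year and tree
#' type, with the derived identities `Td = Tp - Ta`,
#' `E = Es + Esn + Ei` and `ETa = Ta + E`, plus the mean transpiration
#' reduction `mean(Td/Tp)` across tree types per year.
#'
#' @param fluxes Daily flux table (or a list of them, one per tree
#'   type) with columns `date`, `P`, `F`, `Ta`, `Tp`, `Es`, `Esn`,
#'   `Ei`, `SWAT`.
#' @param tree_type Tree type label(s) matching `fluxes`.
#' @param allow_partial Allow years with fewer than 365 days.
#' @return List with `budget` (data.frame, one row per year x tree
#'   type) and `reduction` (data.frame: year, mean Td/Tp across types).
#' @export
annual_budget <- function(fluxes, tree_type = "all",
                          allow_partial = FALSE) {
  if (is.data.frame(fluxes)) fluxes <- list(fluxes)
  if (length(tree_type) != length(fluxes))
    stop("one tree_type label per flux table required")
  rows <- list()
  for (t in seq_along(fluxes)) {
    f <- fluxes[[t]]
    key <- format(as.Date(f$date), "%Y")
    for (y in unique(key)) {
      fy <- f[key == y, ]
      if (nrow(fy) < 365 && !allow_partial)
        stop("year ", y, " is incomplete; set allow_partial = TRUE")
      s <- function(v) sum(fy[[v]])
      e <- s("Es") + s("Esn") + s("Ei")
      rows[[length(rows) + 1]] <- data.frame(
        year = y, tree = tree_type[t], P = s("P"), F = s("F"),
        ETa = s("Ta") + e, Ta = s("Ta"), Tp = s("Tp"),
        Td = s("Tp") - s("Ta"), Es = s("Es"), Esn = s("Esn"),
        Ei = s("Ei"), E = e, SWAT_end = fy$SWAT[nrow(fy)])
    }
  }
  budget <- do.call(rbind, rows)
  years <- unique(budget$year)
  red <- data.frame(year = years, reduction = vapply(years, function(y) {
    b <- budget[budget$year == y, ]
    mean(ifelse(b$Tp > 0, b$Td / b$Tp, NA_real_))
  }, numeric(1)))
  list(budget = budget, reduction = red)
}

#' Drought index series from a simulation
#'
#' Monthly aggregation of the physiological drought indices: `Ta/Tp`
#' (and its minimum daily value), transpiration deficit, end-of-month
#' ADEF and RELAWAT, and the mean rooting-zone matric potential.
#'
#' @param run A [run_simulation()] result.
#' @param drop_spinup Exclude spin-up years (default `TRUE`).
#' @return data.frame: `period`, `ta_tp`, `ta_tp_min_daily`, `td_mm`,
#'   `adef_mm`, `relawat`, `psi_rootzone_kpa`.
#' @export
drought_index_series <- function(run, drop_spinup = TRUE) {
  f <- run$fluxes
  psi <- run$psi
  if (drop_spinup) {
    keep <- !f$spinup
    f <- f[keep, ]; psi <- psi[keep, , drop = FALSE]
  }
  key <- .period_key(f$date, "month")
  rat <- ta_tp_ratio(f, "month")
  td <- transpiration_deficit(f, "month")
  months <- rat$period
  adef_v <- rel_v <- psr <- numeric(length(months))
  for (j in seq_along(months)) {
    i_last <- max(which(key == months[j]))
    mpsi <- colMeans(psi[which(key == months[j]), , drop = FALSE])
    adef_v[j] <- adef(psi[i_last, ], run$column)
    rel_v[j] <- relawat(psi[i_last, ], run$column)
    psr[j] <- psi_rootzone(mpsi, run$column)
  }
  data.frame(period = months, ta_tp = rat$ta_tp,
             ta_tp_min_daily = rat$ta_tp_min_daily, td_mm = td$td_mm,
             adef_mm = adef_v, relawat = rel_v, psi_rootzone_kpa = psr)
}
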