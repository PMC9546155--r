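# Phenology, seasonal leaf area, and root depth distribution.

#' Phenology parameters
#'
#' @param t_base Degree-day base temperature (degC), default 5.
#' @param dd_required Degree-day sum required for budburst (degC day).
#' @param start_doy Day-of-year at which degree-day accumulation starts.
#' @param end_temp_threshold Trailing-window mean temperature (degC) below
#'   which the growing season is taken to end.
#' @param end_window_days Width of the trailing window (days).
#' @param end_earliest_doy Earliest admissible season end.
#' @param end_fallback_doy Season end used when the temperature rule never
#'   fires (default 280).
#' @return Named list of class `phenology_params`.
#' @export
phenology_params <- function(t_base = 5, dd_required = 100, start_doy = 1,
                             end_temp_threshold = 10, end_window_days = 7,
                             end_earliest_doy = 200, end_fallback_doy = 280) {
  if (dd_required < 0) stop("dd_required must be >= 0")
  if (start_doy < 1 || start_doy > 366) stop("start_doy must be in [1, 366]")
  structure(list(t_base = t_base, dd_required = dd_required,
                 start_doy = start_doy,
                 end_temp_threshold = end_temp_threshold,
                 end_window_days = end_window_days,
                 end_earliest_doy = end_earliest_doy,
                 end_fallback_doy = end_fallback_doy),
            class = "phenology_params")
}

#' Budburst day-of-year from a degree-day sum
#'
#' First day (counting from `start_doy`) on which the cumulative sum of
#' max(0, T - t_base) reaches `dd_required`.
#'
#' @param daily_tmean Numeric vector of daily mean temperatures for one
#'   calendar year (length >= 365).
#' @param p A [phenology_params()] object.
#' @return Day-of-year, or `NA_integer_` if the sum is never reached.
#' @export
budburst_doy <- function(daily_tmean, p = phenology_params()) {
  if (length(daily_tmean) < 365)
    stop("daily_tmean must cover at least one calendar year")
  if (p$dd_required == 0) return(p$start_doy)
  idx <- p$start_doy:length(daily_tmean)
  dd <- cumsum(pmax(0, daily_tmean[idx] - p$t_base))
  hit <- which(dd >= p$dd_required)
  if (!length(hit)) return(NA_integer_)
  as.integer(idx[hit[1]])
}

#' Season end day-of-year from a trailing temperature window
#'
#' First day at or after `end_earliest_doy` whose trailing
#' `end_window_days`-day mean temperature falls below
#' `end_temp_threshold`; falls back to `end_fallback_doy` if the rule
#' never fires.
#'
#' @inheritParams budburst_doy
#' @return Day-of-year (always defined).
#' @export
season_end_doy <- function(daily_tmean, p = phenology_params()) {
  if (length(daily_tmean) < 365)
    stop("daily_tmean must cover at least one calendar year")
  w <- p$end_window_days
  nmax <- length(daily_tmean)
  for (d in max(p$end_earliest_doy, w):nmax) {
    if (mean(daily_tmean[(d - w + 1):d]) < p$end_temp_threshold)
      return(as.integer(d))
  }
  as.integer(p$end_fallback_doy)
}

#' Seasonal course of leaf area index for one year
#'
#' Winter plateau at `winter_fraction * maxlai`, linear rise to `maxlai`
#' over `ramp_days` starting at budburst, summer plateau, and linear
#' decline over `ramp_days` ending at `season_end`. Ramps are shortened
#' symmetrically when they would overlap.
#'
#' @param budburst,season_end Day-of-year bounds of the green season
#'   (budburst < season_end).
#' @param maxlai Maximum leaf area index (m2/m2).
#' @param winter_fraction Fraction of `maxlai` retained in winter
#'   (0 deciduous, ~0.8 evergreen).
#' @param ramp_days Length of the green-up and senescence ramps (days).
#' @param n_days Days in the year (365 or 366).
#' @return Numeric vector of daily LAI of length `n_days`.
#' @export
lai_course <- function(budburst, season_end, maxlai, winter_fraction = 0,
                       ramp_days = 20, n_days = 365) {
  if (winter_fraction >= 1) return(rep(maxlai, n_days))
  if (is.na(budburst)) return(rep(winter_fraction * maxlai, n_days))
  if (budburst >= season_end) stop("budburst must precede season_end")
  season <- season_end - budburst
  ramp <- min(ramp_days, floor(season / 2))
  lo <- winter_fraction * maxlai
  lai <- rep(lo, n_days)
  doy <- seq_len(n_days)
  up <- doy >= budburst & doy < budburst + ramp
  lai[up] <- lo + (maxlai - lo) * (doy[up] - budburst) / ramp
  mid <- doy >= budburst + ramp & doy <= season_end - ramp
  lai[mid] <- maxlai
  dn <- doy > season_end - ramp & doy <= season_end
  lai[dn] <- maxlai - (maxlai - lo) * (doy[dn] - (season_end - ramp)) / ramp
  lai
}

#' Per-layer relative root length density (beta depth model)
#'
#' The cumulative root proportion above depth d (m) follows
#' Y(d) = 1 - betaroot^(100 d) (exponent in cm). Per-layer fractions are
#' Y differences truncated at the maximum rooting depth and renormalized
#' to sum to 1; layers entirely below the rooting depth get 0.
#'
#' @param betaroot Shape parameter in (0, 1); larger values put more roots
#'   at depth.
#' @param maxrootdepth Maximum rooting depth (m, > 0).
#' @param layer_bounds Ascending depth bounds starting at 0 (m), length
#'   `n_layers + 1`.
#' @return Numeric vector of per-layer fractions summing to 1.
#' @export
root_fractions <- function(betaroot, maxrootdepth, layer_bounds) {
  if (betaroot <= 0 || betaroot >= 1) stop("betaroot must be in (0, 1)")
  if (maxrootdepth <= 0) stop("maxrootdepth must be > 0")
  if (any(diff(layer_bounds) <= 0) || abs(layer_bounds[1]) > 1e-12)
    stop("layer_bounds must ascend from 0")
  if (maxrootdepth <= layer_bounds[1] + 1e-12)
    stop("maxrootdepth must exceed the first layer top")
  Y <- function(d) 1 - betaroot^(100 * pmin(d, maxrootdepth))
  top <- layer_bounds[-length(layer_bounds)]
  bot <- layer_bounds[-1]
  f <- Y(bot) - Y(top)
  tot <- sum(f)
  if (tot <= 0) stop("no roots above maxrootdepth")
  f / tot
}
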