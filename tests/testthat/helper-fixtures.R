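# Shared fixtures: a reference retention-curve parameter set, a worked
# one-horizon profile, and small builders used across test files.

ref_mvg <- function() mvg_params(theta_r = 0.05, theta_s = 0.45,
                                 alpha = 0.01, n = 1.5, ksat = 100)

# homogeneous 1 m loam horizon with 20% gravel (worked storage example)
ref_profile <- function(bottom = 1, gravel = 0.2) {
  data.frame(top_m = 0, bottom_m = bottom, sand_pct = 40, silt_pct = 40,
             clay_pct = 20, gravel_frac = gravel, bd_gcm3 = 1.4,
             corg_pct = 1)
}

ref_column <- function(nlay_depth = 0.5, gravel = 0) {
  soil_column(ref_profile(bottom = nlay_depth, gravel = gravel),
              list(ref_mvg()), betaroot = 0.95,
              maxrootdepth = nlay_depth)
}

ref_site <- function(tree_type = "deciduous") {
  list(lat = 47, elevation = 600, slope = 0, aspect = 180,
       tree_type = tree_type, height = 25, maxlai = 4.6)
}

# small synthetic site used by several simulation tests
ref_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      meteo <- gen_meteo(climate_spec(), n_years = 2, seed = 42)
      profile <- gen_profile("deep_loam", seed = 42)
      col <- soil_column(profile, apply_ptf(profile, "wessolek"),
                         betaroot = 0.96, maxrootdepth = 1.2)
      cache <<- run_simulation(meteo, ref_site(), column = col,
                               spinup_years = 1)
    }
    cache
  }
})

# daily flux table whose annual sums match the given annual totals
annual_series <- function(year, P, F, Ta, Tp, Es, Esn, Ei, swat = 300) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  n <- length(dates)
  spread <- function(total) rep(total / n, n)
  data.frame(date = dates, P = spread(P), F = spread(F), Ta = spread(Ta),
             Tp = spread(Tp), Es = spread(Es), Esn = spread(Esn),
             Ei = spread(Ei), SWAT = rep(swat, n))
}
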