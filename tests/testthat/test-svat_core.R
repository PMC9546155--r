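test_that("precipitation partitions hard at the threshold temperature", {
  expect_equal(partition_precip(10, -5, 0), list(rain = 0, snowfall = 10))
  expect_equal(partition_precip(10, 5, 0), list(rain = 10, snowfall = 0))
  expect_equal(partition_precip(0, -20, 0), list(rain = 0, snowfall = 0))
  pp <- partition_precip(c(3, 7), c(-1, 1), 0)
  expect_equal(pp$rain + pp$snowfall, c(3, 7))
  expect_error(partition_precip(-1, 0), ">= 0")
})

test_that("degree-day snow melts and conserves mass", {
  st <- snow_step(20, 0, 5, melt_coef = 2)
  expect_equal(st$melt, 10)
  expect_equal(st$swe, 10)
  expect_equal(snow_step(20, 0, -3)$melt, 0)
  z <- snow_step(0, 0, 10)
  expect_equal(unlist(z), c(swe = 0, melt = 0, esn = 0))
  st2 <- snow_step(5, 3, 2, melt_coef = 2, esn_potential = 1)
  expect_equal(st2$swe + st2$melt + st2$esn, 5 + 3, tolerance = 1e-12)
})

test_that("canopy interception fills, overflows and evaporates", {
  ic <- interception_step(10, 0, 5)
  expect_equal(ic$throughfall, 10)
  expect_equal(ic$ei, 0)
  ic2 <- interception_step(10, 4, 2, storage = 0, cap_lai = 1)
  expect_equal(ic2$throughfall, 6)
  expect_equal(ic2$ei, 2)
  expect_equal(ic2$storage, 2)
  set.seed(3)
  storage <- 0
  for (k in 1:50) {
    rain <- rgamma(1, 0.7, scale = 4)
    ic3 <- interception_step(rain, runif(1, 0, 6), runif(1, 0, 2), storage)
    expect_equal(rain, ic3$throughfall + (ic3$storage - storage) + ic3$ei,
                 tolerance = 1e-12)
    storage <- ic3$storage
  }
})

test_that("conductance reductions halve at their reference points", {
  expect_equal(conductance_f_radiation(100, 100), 0.5)
  expect_equal(conductance_f_vpd(2, 2), 0.5)
  expect_equal(conductance_f_vpd(0, 2), 1)
})

test_that("two-source potential fluxes behave with leaf area", {
  meteo <- prepare_meteo(gen_meteo(climate_spec(), 1, seed = 9))
  plant <- plant_params()
  site <- ref_site()
  d <- which(meteo$doy == 180)
  m1 <- meteo[d, , drop = FALSE]
  p0 <- potential_fluxes(m1, 0, plant, site)
  expect_equal(p0$tp, 0)
  p2 <- potential_fluxes(m1, 2, plant, site)
  p5 <- potential_fluxes(m1, 5, plant, site)
  expect_gt(p5$tp, p2$tp)
  expect_lt(p5$ep_soil, p2$ep_soil)     # canopy shades the soil
  expect_gte(p0$ep_soil, p2$ep_soil)
  expect_true(all(c(p2$tp, p2$ep_soil, p2$ep_int) >= 0))
})

test_that("supply rate reduces to plant conductance algebra", {
  col <- ref_column()
  plant <- plant_params(mxkpl = 8, psicr = -2, fxylem = 0.5, rhiz_c = 1e12)
  n <- nrow(col$layers)
  expect_equal(supply_rate(rep(-2000, n), col, plant)$smax, 0)
  # uniform wet profile, negligible rhizosphere resistance
  sup <- supply_rate(rep(-100, n), col, plant)
  expect_equal(sup$smax, 8 * (-0.1 - (-2)), tolerance = 1e-6)
  expect_equal(sum(sup$weights), 1, tolerance = 1e-12)
  # wetter layers never lose supply when given more roots
  psi <- seq(-50, -1500, length.out = n)
  s1 <- supply_rate(psi, col, plant)$smax
  col2 <- col
  col2$layers$rootfrac[1] <- col2$layers$rootfrac[1] * 2
  col2$layers$rootfrac <- col2$layers$rootfrac / sum(col2$layers$rootfrac)
  expect_gte(supply_rate(psi, col2, plant)$smax, s1 - 1e-9)
})

test_that("half-sine transpiration integral matches its closed form", {
  expect_equal(actual_transpiration(4, 1000, 14)$ta, 4)
  expect_equal(actual_transpiration(4, 0, 14)$ta, 0)
  # supply at half the peak demand rate
  dl <- 14; tp <- 4
  peak <- pi * tp / (2 * dl)                       # mm/h
  s_half <- peak / 2 * 24                          # mm/day
  frac <- ((2 / pi) * (1 - cos(pi / 6)) + 1 / 3) / (2 / pi)
  expect_equal(frac, 0.658, tolerance = 1e-3)
  expect_equal(actual_transpiration(tp, s_half, dl)$ta, frac * tp,
               tolerance = 1e-9)
  w <- c(0.25, 0.75)
  at <- actual_transpiration(tp, s_half, dl, weights = w)
  expect_equal(sum(at$rwu), at$ta, tolerance = 1e-12)
})

test_that("soil evaporation is capped and moisture limited", {
  expect_equal(soil_evaporation(0, 0.3, 0.3), 0)
  es_fc <- soil_evaporation(3, 0.3, 0.3, rssa = 800, r_ref = 150)
  expect_equal(es_fc, 3 * 150 / (150 + 800), tolerance = 1e-12)
  expect_lt(soil_evaporation(3, 0.15, 0.3), es_fc)
  expect_lte(soil_evaporation(3, 0.3, 0.3), 3)
})

test_that("infiltration distributes by the depth power law and conserves water", {
  col <- ref_column()
  src <- infiltrate(10, col, ilayer = 1)
  expect_equal(src[1], 10)
  expect_equal(sum(src[-1]), 0)
  # two equal layers, linear cumulative: 50/50
  src2 <- infiltrate(10, col, ilayer = 2, infexp = 1)
  expect_equal(src2[1:2], c(5, 5), tolerance = 1e-12)
  set.seed(5)
  for (k in 1:20) {
    amt <- runif(1, 0, 50)
    s <- infiltrate(amt, col, sample(nrow(col$layers), 1), runif(1, 0, 3))
    expect_equal(sum(s), amt, tolerance = 1e-12)
    expect_true(all(s >= 0))
  }
})

test_that("Richards step holds equilibrium, conserves a sealed column, and drains at Ksat", {
  col <- ref_column()
  n <- nrow(col$layers)
  zero <- rep(0, n)
  # hydrostatic equilibrium: total potential uniform -> nothing moves
  zmid <- (col$layers$top_m + col$layers$bottom_m) / 2 * 1000
  psi_eq <- -20 + (zmid - zmid[1]) / 101.97
  st <- richards_step(psi_eq, col, zero, zero, flow_params(drain = 0), 1)
  expect_lt(max(abs(st$psi - psi_eq)), 1e-8)
  # sealed column conserves total water over a year of redistribution
  psi <- rep(-30, n)
  w0 <- soil_water_mm(psi, col)
  for (d in 1:365)
    psi <- richards_step(psi, col, zero, zero, flow_params(drain = 0),
                         1)$psi
  expect_lt(abs(soil_water_mm(psi, col) - w0), 1e-6)
  # saturated free-draining column: unit-gradient flux at Ksat
  st2 <- richards_step(rep(0, n), col, zero, zero, flow_params(drain = 1),
                       1e-4)
  expect_equal(st2$drainage / 1e-4, 100, tolerance = 0.05)
})

test_that("simulated fluxes close the daily and annual water balance", {
  run <- ref_run()
  f <- run$fluxes
  mb <- mass_balance(run)
  expect_lt(max(abs(mb)), 1e-6)
  expect_lt(abs(sum(mb)), 1e-3)
  expect_true(all(f$Ta <= f$Tp + 1e-9))
  expect_equal(f$Td, f$Tp - f$Ta)
  expect_equal(f$ETa, f$Ta + f$Es + f$Esn + f$Ei, tolerance = 1e-12)
  expect_true(all(run$psi <= 0))
  flux_cols <- c("P", "F", "ETa", "Ta", "Tp", "Es", "Esn", "Ei")
  expect_true(all(as.matrix(f[flux_cols]) >= -1e-12))
  expect_true(all(f$spinup == (f$year == min(f$year))))
})

test_that("a dry run from the stomatal closure point transpires nothing", {
  meteo <- gen_meteo(climate_spec(), 1, seed = 2)
  meteo$prec <- 0
  col <- ref_column()
  plant <- plant_params(psicr = -2)
  run <- run_simulation(meteo, ref_site(), plant = plant, column = col,
                        psi_init = -2000)
  expect_lt(sum(run$fluxes$Ta), 1e-6)
  expect_lt(sum(run$fluxes$F), 1e-2)
})

test_that("more precipitation never reduces annual streamflow", {
  meteo <- gen_meteo(climate_spec(), 2, seed = 8)
  profile <- gen_profile("deep_loam", seed = 8)
  col <- soil_column(profile, apply_ptf(profile, "wessolek"), 0.96, 1.2)
  r1 <- run_simulation(meteo, ref_site(), column = col, spinup_years = 1)
  meteo2 <- meteo
  meteo2$prec <- meteo2$prec * 2
  r2 <- run_simulation(meteo2, ref_site(), column = col, spinup_years = 1)
  f1 <- sum(r1$fluxes$F[!r1$fluxes$spinup])
  f2 <- sum(r2$fluxes$F[!r2$fluxes$spinup])
  expect_gte(f2, f1)
})

test_that("broken forcing is rejected", {
  meteo <- gen_meteo(climate_spec(), 1, seed = 2)
  gappy <- meteo[-50, ]
  expect_error(run_simulation(gappy, ref_site(), column = ref_column()),
               "consecutive")
  bad <- meteo
  bad$tmin[10] <- bad$tmax[10] + 5
  expect_error(run_simulation(bad, ref_site(), column = ref_column()),
               "tmin")
})
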